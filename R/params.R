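## Utilities over nested parameter trees (lists of numeric arrays).
## A "path" is the dot-joined chain of list names/indices to one leaf array.

param_paths <- function(tree, prefix = character(0)) {
  if (is.numeric(tree)) return(list(prefix))
  out <- list()
  nm <- names(tree)
  for (i in seq_along(tree)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    out <- c(out, param_paths(tree[[i]], c(prefix, key)))
  }
  out
}

## resolve one key: by name when the list has that name, else positionally
## (paths store unnamed positions as their index printed as a string)
leaf_key <- function(tree, k) {
  if (!is.null(names(tree)) && k %in% names(tree)) return(k)
  i <- suppressWarnings(as.integer(k))
  if (is.na(i) || i < 1L || i > length(tree))
    stop("no parameter component '", k, "'")
  i
}

get_leaf <- function(tree, path) {
  for (k in path) tree <- tree[[leaf_key(tree, k)]]
  tree
}

set_leaf <- function(tree, path, value) {
  k <- leaf_key(tree, path[1])
  if (length(path) == 1L) {
    tree[[k]] <- value
    return(tree)
  }
  tree[[k]] <- set_leaf(tree[[k]], path[-1], value)
  tree
}

path_key <- function(path) paste(path, collapse = ".")

## TRUE for leaves subject to L2 weight decay (kernels and weight matrices,
## not biases)
is_weight_path <- function(path) {
  leafish <- path[length(path)]
  if (leafish %in% c("W", "b")) return(leafish == "W")
  parent <- if (length(path) >= 2L) path[length(path) - 1L] else ""
  if (parent %in% c("W", "b")) return(parent == "W")
  startsWith(leafish, "W")
}

## sum of squares over all decayed leaves
l2_penalty <- function(tree) {
  s <- 0
  for (p in param_paths(tree))
    if (is_weight_path(p)) s <- s + sum(get_leaf(tree, p)^2)
  s
}

## elementwise tree combination: out = f(a_leaf, b_leaf)
tree_map2 <- function(a, b, f) {
  for (p in param_paths(a)) a <- set_leaf(a, p, f(get_leaf(a, p), get_leaf(b, p)))
  a
}

tree_zero <- function(tree) {
  for (p in param_paths(tree)) {
    leaf <- get_leaf(tree, p)
    tree <- set_leaf(tree, p, leaf * 0)
  }
  tree
}
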