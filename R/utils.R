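# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and counters; keeps results < 2^31.
derive_seed <- function(master, ...) {
  counters <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (k in counters) {
    # affine counter mixing (Weyl-style); coefficients coprime with the modulus
    s <- (s * 48271 + as.numeric(k) * 65537 + 12345) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 &&
  abs(x - round(x)) < 1e-8

# --- parameter-tree utilities -------------------------------------------------
# Model parameters and their gradients are nested named lists whose leaves are
# numeric vectors/matrices/arrays; these map over that structure.

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

# When both subtrees are named, children are matched by name (gradient trees
# may list leaves in a different order than the parameter tree).
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    nm <- names(a)
    out <- vector("list", length(a))
    names(out) <- nm
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && nzchar(nm[i]) && !is.null(names(b))) b[[nm[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    return(out)
  }
  f(a, b)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_sum <- function(f, a) {
  if (is.list(a)) return(sum(vapply(a, function(x) tree_sum(f, x), numeric(1))))
  f(a)
}

tree_n_params <- function(a) tree_sum(length, a)
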