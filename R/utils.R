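# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched so partial pipeline runs stay reproducible.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a sub-stream seed from a master seed and a stage label; keeps all
# derived seeds inside the 32-bit integer range.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided Mann-Whitney with the degenerate all-tied case defined as
# U = n1*n2/2, p = 1 (exchangeable groups), exact p when the smaller group
# has <= exact_max values and there are no ties.
safeWilcox <- function(x, y, exact_max = 8L) {
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  w <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(w$statistic), p = w$p.value)
}

# Compact letter display from a symmetric logical "significantly different"
# matrix (insertion-absorption algorithm): groups sharing a letter are not
# significantly different.
compactLetters <- function(diffmat) {
  n <- nrow(diffmat)
  groups <- list(seq_len(n))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (!diffmat[i, j]) next
    for (g in seq_along(groups)) {
      if (all(c(i, j) %in% groups[[g]])) {
        gi <- setdiff(groups[[g]], j)
        gj <- setdiff(groups[[g]], i)
        groups[[g]] <- gi
        if (!any(vapply(groups, function(h) all(gj %in% h), TRUE)))
          groups <- c(groups, list(gj))
      }
    }
    keep <- !vapply(seq_along(groups), function(g)
      any(vapply(groups[-g], function(h) all(groups[[g]] %in% h), TRUE)),
      TRUE)
    groups <- groups[keep]
  }
  ord <- order(vapply(groups, min, 1L))
  groups <- groups[ord]
  out <- character(n)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  names(out) <- rownames(diffmat)
  out
}
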