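#' @importFrom stats sd median var cor quantile rnorm runif rlnorm setNames
#' @importFrom stats prcomp kmeans hclust dist cutree as.dendrogram order.dendrogram
#' @importFrom stats pt pf pchisq pnorm p.adjust lm lm.fit coef resid anova
#' @importFrom stats wilcox.test bartlett.test cor.test mahalanobis cov dnorm
#' @importFrom stats complete.cases aggregate
#' @importFrom methods new validObject is slot
#' @importFrom utils head tail write.table read.table
NULL

## Deterministic child-seed derivation: one root seed fans out to named
## streams so that, e.g., adding genes does not perturb trait draws.
## Kept below 2^31 - 1 (R integers are 32-bit).
childSeed <- function(root, stream) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(root) * 48271 + h * 1299721) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## z-score columns; constant columns become zeros (with optional warning)
zscoreCols <- function(x, warn = TRUE) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    if (warn) warning("constant column(s) scaled to zero: ",
                      paste(colnames(x)[bad], collapse = ", "))
    s[bad] <- 1
  }
  out <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  out[, bad] <- 0
  out
}

## z-score rows (genes); constant rows become zeros
zscoreRows <- function(x, warn = TRUE) t(zscoreCols(t(x), warn = warn))

stopIfNot1 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## rbind a list of data.frames; empty input gives the supplied prototype
rbindRows <- function(rows, empty) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
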