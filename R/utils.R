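#' Pathological stage labels, in progression order
#'
#' The serrated pathway orders lesions normal < HP < SSL < SSLD < TSA < tumor
#' (hyperplastic polyp, sessile serrated lesion, SSL with dysplasia,
#' traditional serrated adenoma).
#'
#' @return Character vector of the six stage labels.
#' @export
stage_levels <- function() {
  c("normal", "HP", "SSL", "SSLD", "TSA", "tumor")
}

#' Chromosome arm labels 1p through 22q
#'
#' @return Character vector of the 44 autosomal arm labels.
#' @export
arm_levels <- function() {
  paste0(rep(1:22, each = 2L), c("p", "q"))
}

#' Map p-values to significance stars
#'
#' Uses the convention NS for p > 0.05, `*` for p < 0.05, `**` for p < 0.01
#' and `***` for p < 0.001 (boundaries fall in the weaker class).
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of the same length with values in
#'   `c("NS", "*", "**", "***")`, NA where `p` is NA.
#' @examples
#' p_stars(c(0.2, 0.03, 0.005, 2e-4))
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- "NS"
  out[ok & p < 0.05] <- "*"
  out[ok & p < 0.01] <- "**"
  out[ok & p < 0.001] <- "***"
  out
}

# Evaluate code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic named substream of a master seed, kept below 2^31 so it is a
# valid R integer. Enabling or disabling one pipeline stage must not perturb
# another stage's randomness, so each stage derives its own seed by label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 9973 + h * 131) %% 2147483587L
}

# Column-wise nonzero counts of a sparse/dense matrix.
col_nnz <- function(x) {
  if (is(x, "sparseMatrix")) {
    x <- as(x, "CsparseMatrix")
    diff(x@p)
  } else {
    colSums(x != 0)
  }
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
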