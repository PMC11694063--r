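#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select group_by summarise ungroup arrange
#'   left_join inner_join anti_join bind_rows bind_cols count rename n
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median quantile sd var dist hclust cutree rnorm runif
#'   rgamma rmultinom rnbinom rlnorm setNames model.matrix glm poisson
#'   pf pchisq p.adjust prcomp cor cmdscale coef predict aov complete.cases
#' @importFrom utils head combn
#' @importFrom methods as
NULL

# Deterministic sub-seed derivation: a small multiplicative hash keeping the
# result a valid 32-bit seed. Sub-draws keyed by (seed, labels...) so stage
# order never changes a stream.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    kv <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    h <- (h * 48271 + kv + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a fixed RNG state without touching the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / k  # all-zero gamma draws only at alpha ~ 0
  x / rowSums(x)
}

assert_that <- function(ok, msg, class = "imcpair_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

assert_prob_vector <- function(p, name, tol = 1e-9) {
  assert_that(is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= tol,
              sprintf("`%s` must be a non-negative vector summing to 1.", name),
              class = "imcpair_validation_error")
}

tissue_sites <- function() c("PT", "bone", "brain", "liver", "soft_tissue")
met_sites <- function() setdiff(tissue_sites(), "PT")
locations <- function() c("intratumoral", "stromal", "margin")
panels <- function() c("tumor", "tcell", "myeloid")
subtypes <- function() c("LumA", "LumB", "HER2", "TN")
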