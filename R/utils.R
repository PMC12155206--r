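#' @importFrom rlang %||% abort warn inform
#' @importFrom stats rnorm rbinom rlnorm rgamma rnbinom rpois rbeta runif
#'   plogis qlogis dnorm sd var cor cor.test prcomp pt uniroot setNames
#'   coef predict glm binomial quantile complete.cases
#' @importFrom utils head
NULL

# Deterministic stage-seed derivation: a master seed plus a stage label map to
# a reproducible integer in [0, 2^31 - 2]. Arithmetic stays below 2^53 so the
# double-precision modulus is exact.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (seed %% m) * 48271 %% m
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney AUC with midrank tie correction: the probability that a
#' randomly chosen positive case receives a higher score than a randomly
#' chosen negative one, counting ties as 1/2. A constant score therefore
#' gives exactly 0.5.
#'
#' @param labels binary vector (0/1, logical, or two-level factor).
#' @param scores numeric scores, higher = more likely positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(labels, scores) {
  y <- as_binary01(labels)
  stopifnot(length(y) == length(scores), !anyNA(scores))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC undefined: labels contain a single class.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary01 <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) {
    abort("labels must be binary (0/1, logical, or a two-level factor).")
  }
  as.integer(labels)
}

# Numeric feature matrix from a tibble/data.frame/matrix, dropping a
# participant_id column when present. Keeps column names.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  if ("participant_id" %in% names(x)) x$participant_id <- NULL
  bad <- !vapply(x, is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric feature columns: ",
                 paste(names(x)[bad], collapse = ", ")))
  }
  as.matrix(x)
}

# Stratified assignment of fold ids 1..k within each class, deterministic
# under the current RNG state.
stratified_folds <- function(labels, k) {
  y <- as_binary01(labels)
  foldid <- integer(length(y))
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}
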