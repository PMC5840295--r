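#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr mutate filter select arrange left_join group_by summarise ungroup
#' @importFrom tibble tibble as_tibble
NULL

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 45.5 -> 46, -45.5 -> -46), matching how percentages and fold
#' ratios are displayed in count tables. Base `round()` uses
#' round-half-even, which is wrong for display granularity checks.
#'
#' @param x numeric vector
#' @param digits integer, decimal places (default 0)
#' @return numeric vector rounded ties-away-from-zero
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a local RNG seed, restoring global state afterwards.
# Keeps generators reproducible without touching the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Extract the numeric count matrix from a wide count tibble whose first
# column is the feature id; remaining columns are runs/samples.
count_matrix <- function(counts, id_col = NULL) {
  stopifnot(is.data.frame(counts))
  id_col <- id_col %||% names(counts)[1]
  ids <- as.character(counts[[id_col]])
  keep <- setdiff(names(counts), c(id_col, "length"))
  m <- as.matrix(counts[keep])
  if (!is.numeric(m)) abort("Count columns must all be numeric.")
  if (any(m < 0, na.rm = TRUE)) abort("Counts must be non-negative.")
  rownames(m) <- ids
  m
}

check_run_meta <- function(counts, run_meta) {
  need <- c("run_id", "construct")
  miss <- setdiff(need, names(run_meta))
  if (length(miss)) {
    abort(paste0("`run_meta` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  m <- count_matrix(counts)
  absent <- setdiff(run_meta$run_id, colnames(m))
  if (length(absent)) {
    abort(paste0("Runs in `run_meta` absent from the count table: ",
                 paste(absent, collapse = ", ")))
  }
  invisible(TRUE)
}

# NB density that degrades gracefully to Poisson as dispersion -> 0.
dnbinom_mu <- function(x, mu, dispersion, log = FALSE) {
  if (dispersion < 1e-8) {
    stats::dpois(x, lambda = mu, log = log)
  } else {
    stats::dnbinom(x, size = 1 / dispersion, mu = mu, log = log)
  }
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion < 1e-8) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
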