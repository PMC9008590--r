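#' @keywords internal
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @useDynLib cyanophen, .registration = TRUE
"_PACKAGE"

# seed locally without clobbering the caller's RNG state
withr_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) {
    rlang::abort("seed must be an integer", class = "cyanophen_invalid_argument")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  invisible(old)
}

check_pedigree_order <- function(pedigree) {
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(pedigree))) {
    rlang::abort("pedigree needs columns id, sire, dam",
                 class = "cyanophen_invalid_argument")
  }
  if (anyDuplicated(pedigree$id)) {
    rlang::abort("pedigree ids must be unique", class = "cyanophen_invalid_argument")
  }
  idx <- seq_len(nrow(pedigree))
  for (col in c("sire", "dam")) {
    p <- match(pedigree[[col]], pedigree$id)
    known <- !is.na(pedigree[[col]])
    if (any(known & is.na(p))) {
      rlang::abort(sprintf("%s ids not present in pedigree", col),
                   class = "cyanophen_invalid_input")
    }
    if (any(p[known] >= idx[known])) {
      rlang::abort("parents must precede offspring (topological order)",
                   class = "cyanophen_invalid_input")
    }
  }
  invisible(TRUE)
}

# batch-means Monte-Carlo standard error of a chain mean; batch size ~ sqrt(n)
mcse <- function(x, n_batches = NULL) {
  n <- length(x)
  n_batches <- min(n_batches %||% max(2, floor(sqrt(n))), n)
  bm <- tapply(x, cut(seq_len(n), n_batches, labels = FALSE), mean)
  stats::sd(bm) / sqrt(length(bm))
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

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
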