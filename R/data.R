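#' Current-trial basket data
#'
#' Container for the observed responses of a single-arm basket trial with a
#' binary endpoint: for each of the `K` baskets, the number of responders
#' `y[k]` out of `n[k]` treated patients.
#'
#' @param y Integer vector of responder counts, one per basket.
#' @param n Integer vector of basket sample sizes, same length as `y`.
#' @param labels Optional character vector of basket names.
#' @return An object of class `basket_data` with elements `K`, `y`, `n`,
#'   `labels`.
#' @examples
#' basket_data(y = c(5, 2, 3, 1, 4), n = rep(34, 5))
#' @export
basket_data <- function(y, n, labels = NULL) {
  if (length(y) != length(n) || length(y) < 1L)
    stop("'y' and 'n' must be non-empty vectors of equal length")
  if (any(!is.finite(y)) || any(!is.finite(n)))
    stop("'y' and 'n' must be finite")
  if (any(n < 0) || any(y < 0) || any(y > n))
    stop("counts must satisfy 0 <= y[k] <= n[k]")
  if (is.null(labels)) labels <- paste0("basket_", seq_along(y))
  structure(list(K = length(y), y = as.numeric(y), n = as.numeric(n),
                 labels = labels),
            class = "basket_data")
}

#' @export
print.basket_data <- function(x, ...) {
  cat("Basket trial data:", x$K, "baskets\n")
  print(data.frame(basket = x$labels, y = x$y, n = x$n,
                   rate = round(x$y / pmax(x$n, 1), 3)), row.names = FALSE)
  invisible(x)
}

#' Historical basket data
#'
#' Per current basket, the responder counts of zero or more completed studies
#' of the same disease type and treatment.  By convention baskets with
#' historical information occupy the leading indices `1..K*`; the constructor
#' enforces this (use [reorder_history()] to permute a data set into that
#' form).
#'
#' @param studies A list of length `K`; element `k` is a list (possibly
#'   empty) of `c(y_star, n_star)` pairs, one per historical study for
#'   basket `k`.
#' @return An object of class `historic_data` with elements `K`, `H`
#'   (number of studies per basket), `K_star`, and `studies`.
#' @examples
#' historic_data(list(list(c(1, 13)), list(c(1, 13)), list(c(1, 13)),
#'                    list(), list()))
#' @export
historic_data <- function(studies) {
  if (!is.list(studies)) stop("'studies' must be a list (one element per basket)")
  studies <- lapply(studies, function(s) {
    if (is.null(s) || length(s) == 0L) return(list())
    if (is.numeric(s) && length(s) == 2L) s <- list(s)
    lapply(s, function(p) {
      p <- as.numeric(p)
      if (length(p) != 2L || any(!is.finite(p)) || p[1] < 0 || p[2] < 0 ||
          p[1] > p[2])
        stop("each historical study must be c(y_star, n_star) with 0 <= y* <= n*")
      p
    })
  })
  H <- vapply(studies, length, integer(1))
  K_star <- sum(H > 0L)
  if (K_star > 0L && any(H[seq_len(K_star)] == 0L))
    stop("baskets with historical data must occupy the leading indices; ",
         "see reorder_history()")
  structure(list(K = length(studies), H = H, K_star = K_star,
                 studies = studies),
            class = "historic_data")
}

#' Empty historical data for K baskets
#' @param K Number of current baskets.
#' @return A `historic_data` object with no studies.
#' @export
no_history <- function(K) {
  historic_data(replicate(K, list(), simplify = FALSE))
}

#' Reorder baskets so those with historical data lead
#'
#' The models index baskets so that the `K*` baskets with historical
#' information come first.  This helper permutes a `(basket_data,
#' historic_data)` pair into that convention and records the permutation.
#'
#' @param data A [basket_data()] object.
#' @param hist A list in the shape accepted by [historic_data()] (history per
#'   basket, in the order of `data`).
#' @return A list with elements `data`, `hist` and `perm` such that
#'   `perm[i]` gives the original index of reordered basket `i`.
#' @export
reorder_history <- function(data, hist) {
  H <- vapply(hist, length, integer(1))
  perm <- order(H == 0L) # stable: history-bearing baskets first
  list(data = basket_data(data$y[perm], data$n[perm], data$labels[perm]),
       hist = historic_data(hist[perm]),
       perm = perm)
}

#' Pool current baskets with their historical counts
#'
#' Adds, for every basket, the summed historical responders and sample sizes
#' to the current counts: `y'_k = y_k + sum_j y*_j`, `n'_k = n_k + sum_j n*_j`.
#' Baskets without history are unchanged.  This is the data preparation step
#' of the pooled analysis (EXNEX fitted to pooled counts).
#'
#' @param data A [basket_data()] object.
#' @param hist A [historic_data()] object with the same number of baskets.
#' @return A [basket_data()] object with pooled counts.
#' @examples
#' d <- basket_data(c(5, 2, 3, 1, 4), rep(34, 5))
#' h <- historic_data(list(list(c(3, 13)), list(), list(), list(), list()))
#' pool_with_history(d, h)
#' @export
pool_with_history <- function(data, hist) {
  stopifnot(inherits(data, "basket_data"), inherits(hist, "historic_data"))
  if (hist$K != data$K) stop("'data' and 'hist' must cover the same baskets")
  y <- data$y
  n <- data$n
  for (k in seq_len(data$K)) {
    for (s in hist$studies[[k]]) {
      y[k] <- y[k] + s[1]
      n[k] <- n[k] + s[2]
    }
  }
  basket_data(y, n, data$labels)
}

#' Unroll historical baskets into trial units
#'
#' Builds the augmented unit list used by the multi-level mixture model: the
#' `K` current baskets (indicator `psi = 0`) followed by every historical
#' basket (`psi = 1`), each tagged with the current basket it belongs to.
#'
#' @inheritParams pool_with_history
#' @return An object of class `augmented_trial` with vectors `y`, `n`, `psi`,
#'   `owner` (1-based index of the owning current basket) and scalar `K`.
#' @export
augment_trial <- function(data, hist) {
  stopifnot(inherits(data, "basket_data"), inherits(hist, "historic_data"))
  if (hist$K != data$K) stop("'data' and 'hist' must cover the same baskets")
  y <- data$y; n <- data$n
  psi <- rep(0L, data$K)
  owner <- seq_len(data$K)
  for (k in seq_len(data$K)) {
    for (s in hist$studies[[k]]) {
      y <- c(y, s[1]); n <- c(n, s[2])
      psi <- c(psi, 1L); owner <- c(owner, k)
    }
  }
  structure(list(K = data$K, y = y, n = n, psi = psi, owner = owner),
            class = "augmented_trial")
}

#' Read basket data from CSV
#'
#' Expects columns `basket_id`, `y`, `n`.
#' @param path Path to a CSV file.
#' @return A [basket_data()] object (baskets in file order).
#' @export
read_basket_data <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("basket_id", "y", "n")
  if (!all(need %in% names(df)))
    stop("basket CSV must have columns: ", paste(need, collapse = ", "))
  basket_data(df$y, df$n, as.character(df$basket_id))
}

#' Read historical data from CSV
#'
#' Expects columns `basket_id`, `study_id`, `y_star`, `n_star`; `basket_id`
#' values must match the labels of `data`.
#' @param path Path to a CSV file.
#' @param data The [basket_data()] object the history attaches to.
#' @return A list in the shape accepted by [historic_data()] (use
#'   [reorder_history()] if the history-bearing baskets do not lead).
#' @export
read_historic_csv <- function(path, data) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("basket_id", "study_id", "y_star", "n_star")
  if (!all(need %in% names(df)))
    stop("historic CSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$basket_id), data$labels)
  if (length(bad))
    stop("unknown basket_id in historic CSV: ", paste(bad, collapse = ", "))
  hist <- replicate(data$K, list(), simplify = FALSE)
  for (i in seq_len(nrow(df))) {
    k <- match(df$basket_id[i], data$labels)
    hist[[k]] <- c(hist[[k]], list(c(df$y_star[i], df$n_star[i])))
  }
  hist
}
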