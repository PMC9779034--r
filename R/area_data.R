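#' Per-area study data
#'
#' Container for an areal count dataset: observed case counts, population
#' at risk, expected counts under indirect standardization (optional until
#' computed) and an area-by-covariate matrix of population proportions.
#'
#' @param area_ids character vector of unique area labels.
#' @param observed non-negative integer case counts, one per area.
#' @param population positive population at risk, one per area.
#' @param expected optional positive expected counts (e.g. supplied
#'   externally from an age-stratified standardization).
#' @param X optional numeric matrix of area-level covariates (areas in
#'   rows).
#' @param covariate_names optional covariate labels; defaults to the
#'   column names of `X`.
#' @return an object of class `area_data`.
#' @examples
#' d <- area_data(c("A", "B"), observed = c(3, 5), population = c(100, 300))
#' smr(expected_counts(d))
#' @export
area_data <- function(area_ids, observed, population, expected = NULL,
                      X = NULL, covariate_names = NULL) {
  area_ids <- as.character(area_ids)
  m <- length(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area id")
  observed <- as.numeric(observed)
  population <- as.numeric(population)
  if (length(observed) != m || length(population) != m) {
    stop("observed and population must have one entry per area")
  }
  if (any(!is.finite(observed)) || any(observed < 0) ||
      any(observed != round(observed))) {
    stop("observed counts must be non-negative integers")
  }
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("populations must be positive")
  }
  if (!is.null(expected)) {
    expected <- as.numeric(expected)
    if (length(expected) != m || any(!is.finite(expected)) || any(expected <= 0)) {
      stop("expected counts must be positive, one per area")
    }
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != m) stop("X must have one row per area")
    if (is.null(covariate_names)) {
      covariate_names <- colnames(X) %||% paste0("cov_", seq_len(ncol(X)))
    }
    colnames(X) <- covariate_names
    rownames(X) <- area_ids
  }
  structure(list(area_ids = area_ids, observed = observed,
                 population = population, expected = expected, X = X,
                 covariate_names = if (is.null(X)) NULL else colnames(X)),
            class = "area_data")
}

#' @export
print.area_data <- function(x, ...) {
  cat("area_data: ", length(x$area_ids), " areas, total observed ",
      sum(x$observed), "\n", sep = "")
  cat("  expected counts: ", if (is.null(x$expected)) "not computed" else
    "computed", "\n", sep = "")
  if (!is.null(x$X)) {
    cat("  covariates: ", ncol(x$X), " (", paste(utils::head(colnames(x$X), 4),
        collapse = ", "), if (ncol(x$X) > 4) ", ..." else "", ")\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.area_data <- function(x, ...) {
  df <- data.frame(area_id = x$area_ids, population = x$population,
                   observed = x$observed, stringsAsFactors = FALSE)
  df$expected <- if (is.null(x$expected)) NA_real_ else x$expected
  if (!is.null(x$X)) df <- cbind(df, as.data.frame(x$X, row.names = NULL))
  df
}

#' Write / read area data as CSV
#'
#' The CSV layout is `area_id,population,expected,observed,<covariates...>`;
#' covariate columns keep their names.
#'
#' @param data an [area_data()] object.
#' @param path CSV file path.
#' @return `write_area_data` returns `path` invisibly; `read_area_data`
#'   returns an [area_data()].
#' @export
write_area_data <- function(data, path) {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_area_data
#' @export
read_area_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "population", "observed")
  if (!all(need %in% names(df))) {
    stop("area data CSV needs columns: ", paste(need, collapse = ", "))
  }
  covs <- setdiff(names(df), c(need, "expected"))
  X <- if (length(covs)) as.matrix(df[covs]) else NULL
  expected <- if ("expected" %in% names(df) && !anyNA(df$expected)) {
    df$expected
  } else NULL
  area_data(df$area_id, df$observed, df$population, expected = expected, X = X)
}

#' Expected counts by indirect standardization
#'
#' Fills the expected count of each area as the cases it would record if
#' it experienced the overall rate of the whole study region:
#' `e_i = population_i * sum(y) / sum(population)`. By construction
#' `sum(e) == sum(y)`, so the population-weighted mean SMR is 1.
#'
#' @param data an [area_data()] with observed counts and populations.
#' @return a new [area_data()] with `expected` filled.
#' @examples
#' d <- area_data(c("A", "B"), c(2, 6), c(100, 300))
#' expected_counts(d)$expected  # (2, 6)
#' @export
expected_counts <- function(data) {
  stopifnot(inherits(data, "area_data"))
  if (sum(data$observed) == 0) {
    stop("no observed cases in any area: the SMR is undefined")
  }
  rate <- sum(data$observed) / sum(data$population)
  data$expected <- data$population * rate
  data
}

#' Standardized morbidity ratio per area
#'
#' `SMR_i = y_i / e_i`: the multiplicative excess of an area's observed
#' burden over its indirectly standardized expectation. Values above 1
#' indicate more cases than the overall rate predicts.
#'
#' @param data an [area_data()] whose expected counts have been computed
#'   (see [expected_counts()]) or supplied.
#' @return named numeric vector of SMRs.
#' @export
smr <- function(data) {
  stopifnot(inherits(data, "area_data"))
  if (is.null(data$expected)) {
    stop("expected counts not computed; call expected_counts() first")
  }
  if (any(data$expected == 0)) {
    stop("zero expected count for area ",
         data$area_ids[which(data$expected == 0)[1]])
  }
  stats::setNames(data$observed / data$expected, data$area_ids)
}

#' Covariate correlation screen
#'
#' Pairwise correlation matrix of area-level covariates, used to spot
#' clusters of variables worth feeding to the factor analysis.
#'
#' @param X numeric matrix (areas in rows, at least two covariate columns).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @examples
#' correlation_matrix(cbind(a = 1:5, b = c(2, 1, 4, 3, 5)))
#' @export
correlation_matrix <- function(X, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two covariates")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X) %||% paste0("cov_", seq_len(ncol(X)))
    stop("constant covariate: ", nm[which(sds == 0)[1]])
  }
  stats::cor(X, method = method)
}

#' Write a correlation matrix as CSV
#' @param R correlation matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(R, path) {
  df <- data.frame(covariate = rownames(R), R, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
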