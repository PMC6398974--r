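# CSV readers/writers. Dialect: comma-separated, UTF-8, '.' decimal,
# header comment lines prefixed '#'. Sensing matrices: first row odorant
# labels, first column receptor labels. Covariances: square with a shared
# label header row/column.

#' Read a sensing matrix from CSV
#'
#' Expects odorant labels in the header row and receptor labels in the
#' first column; the numeric body is receptors-by-odorants. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @return A [sensing_matrix].
#' @export
read_sensing_matrix <- function(path) {
  df <- read_labeled_csv(path)
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric entries in column '", colnames(df)[bad], "' of ", path)
  }
  sensing_matrix(M)
}

#' Read an odor-environment covariance from CSV
#'
#' Expects a square numeric matrix with the same labels on rows and
#' columns. The matrix is symmetrized (max relative asymmetry `1e-8`) and
#' PSD-validated, with eigenvalues down to `-1e-10` of the largest clipped
#' to zero. An optional side file provides the mean concentration vector.
#'
#' @param path Path to the covariance CSV.
#' @param c0_path Optional path to a one-column CSV of mean concentrations.
#' @return An [odor_environment].
#' @export
read_covariance <- function(path, c0_path = NULL) {
  df <- read_labeled_csv(path)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop("covariance in ", path, " is not square: ",
         nrow(M), " x ", ncol(M))
  }
  if (!is.numeric(M)) stop("non-numeric entries in ", path)
  c0 <- NULL
  if (!is.null(c0_path)) {
    cdf <- utils::read.csv(c0_path, comment.char = "#")
    c0 <- as.numeric(cdf[[ncol(cdf)]])
  }
  odor_environment(M, c0 = c0, odorant_labels = rownames(M))
}

#' Read a noise profile from CSV
#'
#' One variance per receptor; the last column of the file is used.
#'
#' @param path Path to the CSV file.
#' @return A [noise_profile].
#' @export
read_noise <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  noise_profile(as.numeric(df[[ncol(df)]]))
}

#' Write an optimization result to CSV
#'
#' Body columns: receptor label, abundance `K`, fraction `K/Ktot`, and the
#' information gradient. Header comment lines record the seed, the total
#' budget, the achieved information and the KKT residual, so a result file
#' is self-describing and reproducible.
#'
#' @param result An `osn_optimum` from [optimal_distribution()].
#' @param path Output path.
#' @param seed Seed to record in the header (optional).
#' @return `path`, invisibly.
#' @export
write_distribution <- function(result, path, seed = NA) {
  stopifnot(inherits(result, "osn_optimum"))
  K <- result$K$K
  labels <- names(K) %||% paste0("receptor_", seq_along(K))
  header <- c(
    sprintf("# olfadapt optimal receptor distribution"),
    sprintf("# seed: %s", format(seed)),
    sprintf("# Ktot: %.17g", result$K$Ktot),
    sprintf("# information_%s: %.17g", if (result$bits) "bits" else "nats",
            result$info),
    sprintf("# kkt_residual: %.6g", result$kkt_residual),
    sprintf("# converged: %s", result$converged)
  )
  df <- data.frame(receptor = labels, K = K, fraction = K / result$K$Ktot,
                   gradient = result$gradient)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read back a distribution written by [write_distribution()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with the body columns; header metadata in
#'   `attr(, "header")`.
#' @export
read_distribution <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  attr(df, "header") <- header
  df
}

#' Write a labeled matrix (sensing or covariance) to CSV
#'
#' @param x A [sensing_matrix], [odor_environment], or labeled matrix.
#' @param path Output path.
#' @param seed Seed to record in a header comment (optional).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, seed = NA) {
  M <- if (inherits(x, "sensing_matrix")) x$S
       else if (inherits(x, "odor_environment")) x$gamma
       else as.matrix(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# olfadapt matrix; seed: %s", format(seed)), con)
  utils::write.csv(as.data.frame(M), con, row.names = TRUE)
  invisible(path)
}

#' Write a dynamics trajectory to CSV
#'
#' One `time` column plus one column per receptor label.
#'
#' @param traj An `osn_dynamics` object.
#' @param path Output path.
#' @param seed Seed to record in the header (optional).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NA) {
  stopifnot(inherits(traj, "osn_dynamics"))
  df <- data.frame(time = traj$times, traj$K_path, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# olfadapt dynamics trajectory; seed: %s", format(seed)),
               sprintf("# kkt_residual_final: %.6g", traj$kkt_residual_final)),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Shared labeled-CSV reader with duplicate-label and raggedness checks.
read_labeled_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, row.names = NULL, check.names = FALSE,
                    comment.char = "#", fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (ncol(df) < 2) stop("expected a label column plus numeric columns in ", path)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) {
    stop("duplicate row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicate column labels in ", path)
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stop("non-numeric cell in ", path, " at row '", labels[bad_row],
           "', column '", colnames(body)[j], "'")
    }
  }
  rownames(body) <- labels
  body
}
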