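#' Predicted aligned error (PAE) matrix
#'
#' N x N matrix of the expected positional error (in Angstrom) of residue i
#' when the predicted and true structures are aligned on residue j. The
#' matrix is generally asymmetric; low off-diagonal blocks indicate residue
#' pairs that are rigid relative to each other.
#'
#' @param values Square numeric matrix of non-negative errors (A).
#' @param max_value Clip ceiling in A (the AFDB convention is 31.75).
#' @return An object of class `"pae_matrix"`: a list with `values` and
#'   `max_value`, validated to be square, within `[0, max_value]` and with
#'   diagonal entries below 1 A.
#' @export
pae_matrix <- function(values, max_value = 31.75) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stop("PAE matrix must be square")
  if (!is.finite(max_value) || max_value <= 0) stop("max_value must be positive")
  if (any(!is.finite(values))) stop("PAE entries must be finite")
  if (any(values < 0)) stop("PAE entries must be non-negative")
  if (any(values > max_value + 1e-9))
    stop("PAE entries exceed the stated ceiling of ", max_value, " A")
  if (any(diag(values) > 1))
    stop("PAE diagonal entries must be <= 1 A (self-error)")
  structure(list(values = values, max_value = as.numeric(max_value)),
            class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d, ceiling %.2f A, median off-diagonal %.2f A\n",
              nrow(x$values), ncol(x$values), x$max_value,
              stats::median(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

#' @export
dim.pae_matrix <- function(x) dim(x$values)

#' Read a PAE matrix from AFDB-dialect JSON
#'
#' Accepts the AlphaFold Protein Structure Database PAE JSON: an object (or a
#' one-element array of objects) with key `predicted_aligned_error` holding a
#' row-major list of lists, and optionally `max_predicted_aligned_error`.
#' A missing ceiling defaults to 31.75 A. Asymmetry of the payload is
#' preserved exactly.
#'
#' @param path Path to the JSON file.
#' @return A [pae_matrix()].
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) stop("cannot read PAE file: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(js)) {
    # one-element array-of-objects form
    payload <- js$predicted_aligned_error[[1]]
    ceiling <- if ("max_predicted_aligned_error" %in% names(js))
      js$max_predicted_aligned_error[[1]] else NULL
  } else {
    payload <- js[["predicted_aligned_error"]]
    ceiling <- js[["max_predicted_aligned_error"]]
  }
  if (is.null(payload))
    stop("not an AFDB PAE JSON: missing key 'predicted_aligned_error'")
  if (is.list(payload)) {
    lens <- lengths(payload)
    if (length(unique(lens)) != 1L || lens[1] != length(payload))
      stop("malformed PAE payload: rows of unequal length or non-square")
    payload <- do.call(rbind, lapply(payload, as.numeric))
  }
  payload <- as.matrix(payload)
  if (nrow(payload) != ncol(payload))
    stop("malformed PAE payload: ", nrow(payload), " rows x ",
         ncol(payload), " cols")
  if (any(payload < 0)) stop("malformed PAE payload: negative entries")
  pae_matrix(payload, max_value = ceiling %||% 31.75)
}

#' Write a PAE matrix as AFDB-dialect JSON
#'
#' @param pae A [pae_matrix()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_pae <- function(pae, path) {
  if (!inherits(pae, "pae_matrix")) stop("pae must be a pae_matrix")
  rows <- lapply(seq_len(nrow(pae$values)), function(i) pae$values[i, ])
  jsonlite::write_json(
    list(predicted_aligned_error = rows,
         max_predicted_aligned_error = pae$max_value),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
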