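#' Construct an activity class
#'
#' An activity class holds the compounds measured against one protein target:
#' a fixed-width binary fingerprint and a pIC50 label per compound. This is
#' the common container consumed by all model-fitting functions.
#'
#' @param class_id Single label identifying the target / class.
#' @param compound_id Character vector of unique compound identifiers.
#' @param fingerprints Integer or numeric 0/1 matrix, one row per compound.
#' @param pic50 Numeric vector of potency labels on the log-molar scale.
#' @return An object of class `activity_class`.
#' @examples
#' cls <- activity_class("toy", c("a", "b"),
#'                       matrix(c(1, 0, 0, 1), 2, 2), c(6.1, 7.3))
#' n_compounds(cls)
#' @export
activity_class <- function(class_id, compound_id, fingerprints, pic50) {
  compound_id <- as.character(compound_id)
  fingerprints <- as.matrix(fingerprints)
  storage.mode(fingerprints) <- "integer"
  pic50 <- as.numeric(pic50)
  if (anyDuplicated(compound_id)) stop("compound_ids must be unique")
  if (nrow(fingerprints) != length(compound_id) ||
      length(pic50) != length(compound_id)) {
    stop("compound_id, fingerprints and pic50 must have matching lengths")
  }
  if (!all(fingerprints %in% c(0L, 1L))) stop("fingerprints must be binary")
  if (!all(is.finite(pic50))) stop("all pic50 values must be finite")
  structure(
    list(class_id = as.character(class_id)[1L],
         compound_id = compound_id,
         fingerprints = fingerprints,
         pic50 = pic50),
    class = "activity_class"
  )
}

#' Number of compounds in an activity class
#' @param cls An `activity_class`.
#' @return Integer count.
#' @export
n_compounds <- function(cls) {
  stopifnot(inherits(cls, "activity_class"))
  length(cls$compound_id)
}

#' Fingerprint width of an activity class
#' @param cls An `activity_class`.
#' @return Integer number of bits.
#' @export
n_bits <- function(cls) {
  stopifnot(inherits(cls, "activity_class"))
  ncol(cls$fingerprints)
}

#' Subset an activity class by row index or compound id
#'
#' @param x An `activity_class`.
#' @param i Integer/logical row indices or character compound ids.
#' @param ... Unused.
#' @return An `activity_class` restricted to the selected compounds. Synthetic
#'   signal metadata (attribute `"signal"`) is carried over unchanged.
#' @export
`[.activity_class` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$compound_id)
    if (anyNA(i)) stop("unknown compound ids in subset")
  }
  out <- activity_class(x$class_id, x$compound_id[i],
                        x$fingerprints[i, , drop = FALSE], x$pic50[i])
  attr(out, "signal") <- attr(x, "signal")
  out
}

#' @export
print.activity_class <- function(x, ...) {
  cat(sprintf("<activity_class> %s: %d compounds, %d-bit fingerprints\n",
              x$class_id, n_compounds(x), n_bits(x)))
  cat(sprintf("  pIC50 range [%.2f, %.2f], median %.2f\n",
              min(x$pic50), max(x$pic50), median(x$pic50)))
  invisible(x)
}

# --- hex fingerprint codec -------------------------------------------------

bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  padded <- c(as.integer(bits), integer(pad))
  bytes <- packBits(as.logical(padded), type = "raw")
  paste(sprintf("%02x", as.integer(bytes)), collapse = "")
}

hex_to_bits <- function(hex, n_bits = NULL) {
  bytes <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                   seq(2, nchar(hex), 2)), 16L))
  bits <- as.integer(rawToBits(bytes))
  if (!is.null(n_bits)) {
    if (n_bits > length(bits)) stop("hex string shorter than requested width")
    bits <- bits[seq_len(n_bits)]
  }
  bits
}

#' Write an activity class to delimited text
#'
#' The on-disk format is a headered CSV with columns
#' `compound_id,pic50,fingerprint`, where the fingerprint is a hex-encoded
#' bit string (least-significant bit first within each byte, zero-padded to a
#' whole number of bytes).
#'
#' @param cls An `activity_class`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_activity_class()]
#' @export
write_activity_class <- function(cls, path) {
  stopifnot(inherits(cls, "activity_class"))
  fp <- apply(cls$fingerprints, 1L, bits_to_hex)
  df <- data.frame(compound_id = cls$compound_id,
                   pic50 = cls$pic50,
                   fingerprint = fp,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity class from delimited text
#'
#' Accepts the CSV dialect written by [write_activity_class()]. A `smiles`
#' column may be supplied instead of (or in addition to) `fingerprint`; in
#' that case fingerprint computation is delegated to the user-supplied
#' `fingerprint_fun` (for example a wrapper around a cheminformatics
#' toolkit), which must map a character vector of SMILES to a 0/1 matrix.
#'
#' @param path Input CSV path.
#' @param class_id Label for the class; defaults to the file name.
#' @param n_bits Optional fingerprint width; when `NULL` the width is the
#'   full capacity of the hex string (a multiple of 8).
#' @param fingerprint_fun Optional function `function(smiles) -> 0/1 matrix`
#'   used when the table carries SMILES but no pre-computed fingerprints.
#' @return An `activity_class`.
#' @export
read_activity_class <- function(path, class_id = NULL, n_bits = NULL,
                                fingerprint_fun = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(class_id)) class_id <- sub("\\.[^.]*$", "", basename(path))
  if (!"pic50" %in% names(df) || !"compound_id" %in% names(df)) {
    stop("activity class table needs `compound_id` and `pic50` columns")
  }
  if ("fingerprint" %in% names(df)) {
    fp <- t(vapply(df$fingerprint, hex_to_bits,
                   integer(if (is.null(n_bits)) nchar(df$fingerprint[1L]) * 4L
                           else n_bits),
                   n_bits = if (is.null(n_bits)) nchar(df$fingerprint[1L]) * 4L
                            else n_bits))
    dimnames(fp) <- NULL
  } else if ("smiles" %in% names(df)) {
    if (is.null(fingerprint_fun)) {
      stop("table has `smiles` but no `fingerprint` column; ",
           "supply `fingerprint_fun` to delegate fingerprinting")
    }
    fp <- fingerprint_fun(df$smiles)
  } else {
    stop("activity class table needs a `fingerprint` or `smiles` column")
  }
  activity_class(class_id, df$compound_id, fp, df$pic50)
}
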