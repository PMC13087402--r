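#' Construct a descriptor table
#'
#' A descriptor table holds one row per compound and one named numeric
#' molecular descriptor per column (2D autocorrelations, connectivity
#' indices, 3D-MoRSE signals, atom-pair flags, ...). Descriptor values are
#' consumed as given; the package never computes descriptors from structures.
#'
#' @param values numeric matrix, compounds in rows, descriptors in columns.
#' @param compound_ids character vector of unique compound labels; defaults
#'   to the rownames of `values`.
#' @param descriptor_names character vector of unique descriptor names;
#'   defaults to the colnames of `values`.
#' @return An object of class `descriptor_table`: a numeric matrix with
#'   compound ids as rownames and descriptor names as colnames. Column order
#'   is significant and preserved by the CSV round-trip.
#' @seealso [read_descriptor_table()], [write_descriptor_table()]
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("descriptor values must be numeric", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("descriptor table must have at least one compound and one descriptor",
         call. = FALSE)
  }
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(values)) {
    stop("length of compound_ids does not match number of rows", call. = FALSE)
  }
  if (length(descriptor_names) != ncol(values)) {
    stop("length of descriptor_names does not match number of columns",
         call. = FALSE)
  }
  dup <- compound_ids[duplicated(compound_ids)]
  if (length(dup)) {
    stop("duplicated compound id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- descriptor_names[duplicated(descriptor_names)]
  if (length(dup)) {
    stop("duplicated descriptor name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite descriptor value at compound '%s', descriptor '%s'",
                 compound_ids[bad[1L]], descriptor_names[bad[2L]]),
         call. = FALSE)
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  structure(values, class = c("descriptor_table", "matrix", "array"))
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors\n",
              nrow(x), ncol(x)))
  utils::str(unclass(x))
  invisible(x)
}

#' Read a descriptor table from CSV
#'
#' The first column is taken as the compound id; the remaining columns must
#' be numeric descriptors named in the header. The dialect is strict:
#' comma-separated, UTF-8, mandatory header, dot decimal separator, no
#' missing cells.
#'
#' @param path path to a CSV file.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty descriptor table in ", path, call. = FALSE)
  }
  ids <- raw[[1L]]
  names_d <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(names_d))
  for (j in seq_along(names_d)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(trimws(col)))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                   bad[1L], names_d[j], path), call. = FALSE)
    }
    vals[, j] <- num
  }
  descriptor_table(vals, compound_ids = ids, descriptor_names = names_d)
}

#' Write a descriptor table to CSV
#'
#' @param table a [descriptor_table()].
#' @param path output path.
#' @param id_column header used for the compound-id column.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, id_column = "compound_id") {
  stopifnot(inherits(table, "descriptor_table"))
  # 17 significant digits so the CSV round-trip is value-identical
  chr <- apply(unclass(table), 2L, function(v) sprintf("%.17g", v))
  if (nrow(table) == 1L) chr <- matrix(chr, nrow = 1L)
  df <- data.frame(rownames(table), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(table))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Descriptor symbols carry typography that differs across sources (the 2D
# atom-pair flag is printed with an en-dash); map ASCII spellings onto the
# canonical form so either is accepted in headers and model files.
.descriptor_aliases <- function() {
  c("B08[C-O]" = "B08[C–O]")
}

#' Canonicalize a descriptor name
#'
#' Resolves known ASCII aliases (e.g. `"B08[C-O]"` for the en-dash form
#' `"B08[C–O]"`). All other names are returned unchanged; matching is
#' otherwise exact and case-sensitive.
#'
#' @param name character vector of descriptor names.
#' @return character vector of canonical names.
#' @export
canonical_descriptor_name <- function(name) {
  al <- .descriptor_aliases()
  hit <- name %in% names(al)
  name[hit] <- al[name[hit]]
  name
}
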