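# Readers/writers for the plain-text formats the package exchanges:
# MatrixMarket counts with id sidecars, delimited counts, spot geometry,
# proportions tables, per-spot value tables, PNG/TIFF rasters.

.guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a genes-by-spots counts matrix
#'
#' Two dialects are supported: MatrixMarket coordinate format
#' (`format = "mtx"`) with one-id-per-line sidecar files for genes and
#' spots, and a delimited table (`format = "delimited"`) whose header row
#' holds spot ids and whose first column holds gene ids. `"auto"` picks by
#' file extension.
#'
#' @param path counts file.
#' @param format `"auto"`, `"mtx"` or `"delimited"`.
#' @param gene_ids_path,spot_ids_path sidecar id files (mtx only).
#' @param sep field separator for the delimited dialect (guessed when NULL).
#' @return An [expression_matrix()] with `layer = "counts"`.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "delimited"),
                        gene_ids_path = NULL, spot_ids_path = NULL,
                        sep = NULL) {
  format <- match.arg(format)
  .stop_if(!file.exists(path), "file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "delimited"
  if (format == "mtx") {
    .stop_if(is.null(gene_ids_path) || is.null(spot_ids_path),
             "mtx format requires gene_ids_path and spot_ids_path sidecars")
    values <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(gene_ids_path)
    spot_ids <- readLines(spot_ids_path)
    .stop_if(nrow(values) != length(gene_ids),
             "gene id sidecar length does not match matrix rows")
    .stop_if(ncol(values) != length(spot_ids),
             "spot id sidecar length does not match matrix columns")
    return(expression_matrix(values, gene_ids, spot_ids, layer = "counts"))
  }
  if (is.null(sep)) sep <- .guess_sep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  bad <- which(nf != nf[1])
  .stop_if(length(bad) > 0,
           "parse error in ", path, ": line ", bad[1] + 0L, " has ", nf[bad[1]],
           " fields, expected ", nf[1])
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    row.names = 1)
  values <- as.matrix(tab)
  .stop_if(!is.numeric(values), "non-numeric entries in counts table")
  expression_matrix(values, rownames(tab), colnames(tab), layer = "counts")
}

#' Write / read an expression matrix as a delimited table
#'
#' @param x an [expression_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @return `write_counts` returns `path` invisibly.
#' @export
write_counts <- function(x, path, sep = ",") {
  .stop_if(!inherits(x, "expression_matrix"), "x must be an expression_matrix")
  tab <- data.frame(gene_id = x$gene_ids,
                    format(x$values, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  colnames(tab) <- c("gene_id", x$spot_ids)
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spot geometry
#'
#' Neutral delimited dialect with header columns `spot_id`, `row_px`,
#' `col_px` and optional `radius_px`. Platform-specific position files
#' (e.g. the tissue-positions table emitted by spot-array pipelines) can be
#' converted to this layout by selecting/renaming columns upstream. A
#' missing radius column defaults to 70 px.
#'
#' @param path delimited file.
#' @param sep separator (guessed when NULL).
#' @param default_radius_px fallback radius, default 70.
#' @return A [spot_geometry()].
#' @export
read_spot_geometry <- function(path, sep = NULL, default_radius_px = 70) {
  .stop_if(!file.exists(path), "file not found: ", path)
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("spot_id", "row_px", "col_px")
  .stop_if(!all(need %in% names(tab)),
           "geometry file must have columns ", paste(need, collapse = ", "))
  radius <- if ("radius_px" %in% names(tab)) tab$radius_px
            else default_radius_px
  spot_geometry(tab$spot_id, cbind(tab$row_px, tab$col_px), radius)
}

#' Write / read a proportions matrix
#'
#' Writes a delimited table with cell types as rows and spots as columns,
#' at full double precision (round-trips to at least 10 significant
#' digits). Invalid simplex columns are refused before anything is written.
#'
#' @param H a [proportions_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @return `write_proportions` returns `path` invisibly; `read_proportions`
#'   returns a [proportions_matrix()].
#' @export
write_proportions <- function(H, path, sep = ",") {
  .stop_if(!inherits(H, "proportions_matrix"),
           "H must be a proportions_matrix")
  # revalidate (floor + sum check) so no out-of-contract table ever lands
  H <- proportions_matrix(pmax(H$values, 1e-12), H$cell_type_ids, H$spot_ids)
  header <- paste(c("cell_type", H$spot_ids), collapse = sep)
  if (ncol(H$values) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- vapply(seq_along(H$cell_type_ids), function(k) {
    paste(c(H$cell_type_ids[k],
            formatC(H$values[k, ], digits = 15, format = "g")),
          collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path, sep = ",") {
  .stop_if(!file.exists(path), "file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    row.names = 1)
  proportions_matrix(as.matrix(tab), rownames(tab), colnames(tab))
}

#' Write / read per-spot scalar values (priors, references)
#'
#' Two-column delimited table `spot_id, value`.
#'
#' @param x a [spot_prior_values()] or a named numeric vector.
#' @param path file path.
#' @param sep field separator.
#' @param source provenance tag used when reading back.
#' @return `read_spot_values` returns a [spot_prior_values()].
#' @export
write_spot_values <- function(x, path, sep = ",") {
  if (inherits(x, "spot_prior_values")) x <- x$values
  .stop_if(is.null(names(x)), "values must be named by spot id")
  tab <- data.frame(spot_id = names(x),
                    value = formatC(as.numeric(x), digits = 15, format = "g"))
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_values
#' @export
read_spot_values <- function(path, sep = NULL, source = "mapped") {
  .stop_if(!file.exists(path), "file not found: ", path)
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  spot_prior_values(tab$spot_id, as.numeric(tab$value), source = source)
}

#' Read a grayscale raster image
#'
#' PNG and TIFF are read through the `png`/`tiff` packages; multi-channel
#' images are collapsed to grayscale by averaging the first three channels.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param microns_per_pixel optional scale annotation.
#' @return An [image_raster()].
#' @export
read_image_raster <- function(path, microns_per_pixel = NULL) {
  .stop_if(!file.exists(path), "file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    .stop_if(!requireNamespace("png", quietly = TRUE),
             "reading PNG requires the 'png' package")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    .stop_if(!requireNamespace("tiff", quietly = TRUE),
             "reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(px)) == 3)
    px <- apply(px[, , seq_len(min(3, dim(px)[3])), drop = FALSE], c(1, 2),
                mean)
  image_raster(px, microns_per_pixel)
}

#' Read a patch probability map
#'
#' Delimited table with header `row0_px, col0_px, height_px, width_px,
#' probability`.
#'
#' @param path delimited file.
#' @param sep separator (guessed when NULL).
#' @return A [patch_probability_map()].
#' @export
read_patch_map <- function(path, sep = NULL) {
  .stop_if(!file.exists(path), "file not found: ", path)
  if (is.null(sep)) sep <- .guess_sep(path)
  patch_probability_map(read.table(path, header = TRUE, sep = sep))
}
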