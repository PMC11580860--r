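#' Spot-by-gene spatial count container
#'
#' A light container for spatially resolved transcriptomics data: a raw UMI
#' count matrix with one row per spot and one column per gene, together with
#' 2-D spatial coordinates for each spot. Library sizes (total UMIs per spot,
#' \eqn{R_i = \sum_g r_{gi}}) are computed at construction and cached.
#'
#' @param counts Non-negative integer matrix, spots in rows, genes in columns.
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   columns (x, y), in arbitrary spatial units.
#' @param gene_ids Optional character vector of gene identifiers (defaults to
#'   column names of `counts`, or `gene1..geneG`).
#' @param spot_ids Optional character vector of spot identifiers.
#' @param lib_size Optional pre-computed library sizes; used to carry the
#'   original library sizes through gene filtering.
#'
#' @return An object of class `spatial_counts`: a list with elements
#'   `counts`, `coords`, `gene_ids`, `spot_ids`, `lib_size`.
#' @export
#' @examples
#' cts <- matrix(rpois(60, 2), nrow = 10)
#' sc <- spatial_counts(cts, cbind(x = runif(10), y = runif(10)))
#' sc
spatial_counts <- function(counts, coords, gene_ids = NULL, spot_ids = NULL,
                           lib_size = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (UMI counts)")
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have exactly two columns (x, y)")
  storage.mode(coords) <- "double"
  n <- nrow(counts)
  G <- ncol(counts)
  if (nrow(coords) != n) {
    stop(sprintf("counts has %d spots but coords has %d rows", n, nrow(coords)))
  }
  if (n < 2L) stop("need at least 2 spots")
  if (G < 1L) stop("need at least 1 gene")
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))
  if (is.null(spot_ids)) spot_ids <- rownames(counts)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(n))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != G) stop("gene_ids length does not match gene count")
  if (length(spot_ids) != n) stop("spot_ids length does not match spot count")
  if (anyDuplicated(gene_ids)) stop("duplicated gene_ids")
  if (anyDuplicated(spot_ids)) stop("duplicated spot_ids")
  if (is.null(lib_size)) lib_size <- rowSums(counts)
  dimnames(counts) <- list(spot_ids, gene_ids)
  colnames(coords) <- c("x", "y")
  structure(
    list(counts = counts, coords = coords, gene_ids = gene_ids,
         spot_ids = spot_ids, lib_size = as.numeric(lib_size)),
    class = "spatial_counts"
  )
}

#' @exportS3Method base::print
print.spatial_counts <- function(x, ...) {
  cat(sprintf("<spatial_counts> %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  coords: x in [%g, %g], y in [%g, %g]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  cat(sprintf("  library size: median %g (range %g-%g)\n",
              stats::median(x$lib_size), min(x$lib_size), max(x$lib_size)))
  invisible(x)
}

#' @export
dim.spatial_counts <- function(x) dim(x$counts)

read_coords_file <- function(coords_path) {
  sep <- if (grepl("\\.csv$", coords_path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(coords_path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(coords_path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  spot_ids <- NULL
  if (has_header) {
    nm <- tolower(names(df))
    xcol <- which(nm %in% c("x", "col", "array_col", "pxl_col") |
                    grepl("col", nm))[1]
    ycol <- which(nm %in% c("y", "row", "array_row", "pxl_row") |
                    grepl("row", nm))[1]
    idcol <- which(!vapply(df, is.numeric, logical(1)))[1]
    if (!is.na(idcol)) spot_ids <- as.character(df[[idcol]])
    if (is.na(xcol) || is.na(ycol)) {
      num <- which(vapply(df, is.numeric, logical(1)))
      if (length(num) < 2) stop("coords file needs two numeric columns")
      xcol <- num[1]; ycol <- num[2]
    }
    coords <- cbind(x = df[[xcol]], y = df[[ycol]])
  } else {
    num <- which(vapply(df, is.numeric, logical(1)))
    if (length(num) < 2) stop("coords file needs two numeric columns")
    chr <- which(!vapply(df, is.numeric, logical(1)))
    if (length(chr) >= 1) spot_ids <- as.character(df[[chr[1]]])
    coords <- cbind(x = df[[num[1]]], y = df[[num[2]]])
  }
  list(coords = coords, spot_ids = spot_ids)
}

read_id_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  as.character(df[[1]])
}

#' Read spatial count data from standard on-disk formats
#'
#' Reads a count matrix (MatrixMarket sparse `.mtx` or dense TSV) together
#' with a spot coordinate file and optional gene/spot identifier files, and
#' orients the matrix spots-by-genes regardless of on-disk orientation. The
#' orientation is resolved by matching one matrix dimension to the number of
#' coordinate rows; a square matrix without id files is ambiguous and raises
#' an error.
#'
#' @param matrix_path Path to the count matrix (`.mtx` or TSV).
#' @param coords_path Path to a CSV/TSV of per-spot coordinates; columns may
#'   be named (`x`/`y` or `row`/`col`) or unnamed (x then y); an optional
#'   non-numeric column is taken as spot ids.
#' @param genes_path,spots_path Optional one-column TSVs of identifiers
#'   (first column used, so 10x-style `features.tsv` works).
#' @param layout `"mtx"` or `"dense_tsv"`; inferred from the file extension
#'   by default.
#' @return A [spatial_counts] object.
#' @export
read_spatial_counts <- function(matrix_path, coords_path,
                                genes_path = NULL, spots_path = NULL,
                                layout = c("auto", "mtx", "dense_tsv")) {
  layout <- match.arg(layout)
  if (layout == "auto") {
    layout <- if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) "mtx" else "dense_tsv"
  }
  cf <- read_coords_file(coords_path)
  n <- nrow(cf$coords)

  if (layout == "mtx") {
    mm <- Matrix::readMM(matrix_path)
    mat <- as.matrix(mm)
    if (any(abs(mat - round(mat)) > 1e-8)) {
      stop("non-integer counts in MatrixMarket file")
    }
  } else {
    first <- readLines(matrix_path, n = 1L)
    fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
    has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
    mat <- as.matrix(utils::read.table(matrix_path, sep = "\t",
                                       header = has_header))
  }

  gene_ids <- if (!is.null(genes_path)) read_id_file(genes_path) else NULL
  spot_ids <- if (!is.null(spots_path)) read_id_file(spots_path) else cf$spot_ids

  if (nrow(mat) == n && ncol(mat) == n) {
    # square: must disambiguate via id files
    if (!is.null(gene_ids) && length(gene_ids) == ncol(mat)) {
      # assume spots x genes as stored
    } else {
      stop("square count matrix: supply genes_path/spots_path to fix the orientation")
    }
  } else if (nrow(mat) == n) {
    # spots x genes as stored
  } else if (ncol(mat) == n) {
    mat <- t(mat)
  } else {
    stop(sprintf("matrix is %d x %d but coords has %d rows: dimension mismatch",
                 nrow(mat), ncol(mat), n))
  }
  spatial_counts(mat, cf$coords, gene_ids = gene_ids, spot_ids = spot_ids)
}

#' Write spatial count data to disk
#'
#' Writes the counts as MatrixMarket `.mtx` (spots x genes) with companion
#' gene/spot id TSVs and a coordinate CSV, mirroring [read_spatial_counts()].
#'
#' @param data A [spatial_counts] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (named list).
#' @export
write_spatial_counts <- function(data, dir) {
  stopifnot(inherits(data, "spatial_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, "counts.mtx"),
    coords = file.path(dir, "coords.csv"),
    genes = file.path(dir, "genes.tsv"),
    spots = file.path(dir, "spots.tsv")
  )
  Matrix::writeMM(Matrix::Matrix(data$counts, sparse = TRUE), paths$matrix)
  utils::write.table(
    data.frame(spot_id = data$spot_ids, x = data$coords[, 1],
               y = data$coords[, 2]),
    paths$coords, sep = ",", row.names = FALSE, quote = FALSE)
  writeLines(data$gene_ids, paths$genes)
  writeLines(data$spot_ids, paths$spots)
  invisible(paths)
}

#' Filter genes by minimum count in a minimum proportion of spots
#'
#' Keeps gene g iff it has at least `min_count` UMIs in at least
#' `ceil(min_prop_spots * n)` spots. The defaults (2 counts in 0.2% of
#' spots) are the conventional Visium pre-filter for GP-based spatially
#' variable gene detection.
#'
#' Library sizes are by default NOT recomputed after filtering, so CPM
#' denominators keep reflecting the full captured transcriptome of each
#' spot; set `recompute_libsize = TRUE` to base them on the surviving genes.
#'
#' @param data A [spatial_counts] object.
#' @param min_count Minimum UMI count per spot to count as "expressed".
#' @param min_prop_spots Minimum proportion of spots (0, 1].
#' @param recompute_libsize Recompute `lib_size` from surviving genes?
#' @return A filtered [spatial_counts] object (original gene order kept).
#' @export
filter_genes <- function(data, min_count = 2, min_prop_spots = 0.002,
                         recompute_libsize = FALSE) {
  stopifnot(inherits(data, "spatial_counts"))
  if (min_count < 1) stop("min_count must be >= 1")
  if (min_prop_spots <= 0 || min_prop_spots > 1) {
    stop("min_prop_spots must be in (0, 1]")
  }
  n <- nrow(data$counts)
  need <- ceiling(min_prop_spots * n)
  keep <- colSums(data$counts >= min_count) >= need
  subset_genes(data, keep, recompute_libsize)
}

#' Filter genes by total UMI count
#'
#' Keeps gene g iff its total UMI count summed across all spots is at least
#' `min_total_umi` (the threshold used for sparse tissues where the
#' proportion-based filter is too permissive).
#'
#' @inheritParams filter_genes
#' @param min_total_umi Minimum total UMI count across spots.
#' @return A filtered [spatial_counts] object.
#' @export
filter_genes_umi <- function(data, min_total_umi = 80,
                             recompute_libsize = FALSE) {
  stopifnot(inherits(data, "spatial_counts"))
  if (min_total_umi < 0) stop("min_total_umi must be >= 0")
  keep <- colSums(data$counts) >= min_total_umi
  subset_genes(data, keep, recompute_libsize)
}

subset_genes <- function(data, keep, recompute_libsize) {
  if (!any(keep)) stop("all genes removed by filter; trend fitting impossible")
  counts <- data$counts[, keep, drop = FALSE]
  lib_size <- if (recompute_libsize) rowSums(counts) else data$lib_size
  spatial_counts(counts, data$coords, gene_ids = data$gene_ids[keep],
                 spot_ids = data$spot_ids, lib_size = lib_size)
}

new_log_expression <- function(values, scale_tag,
                               pseudocount_numerator = 0.5,
                               pseudocount_denominator = 1) {
  if (any(!is.finite(values))) stop("log-expression values must be finite")
  structure(
    list(values = values, scale_tag = scale_tag,
         pseudocount_numerator = pseudocount_numerator,
         pseudocount_denominator = pseudocount_denominator),
    class = "log_expression"
  )
}

#' @exportS3Method base::print
print.log_expression <- function(x, ...) {
  cat(sprintf("<log_expression> %d spots x %d genes (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' Log2 counts-per-million transform
#'
#' Computes \eqn{y_{gi} = \log_2\{(r_{gi} + 0.5) / (R_i + 1) \times 10^6\}}.
#' The 0.5 pseudocount on the count and 1 on the library size guarantee
#' \eqn{0 < (r_{gi}+0.5)/(R_i+1) < 1} whenever \eqn{r_{gi} \le R_i}, so the
#' log never sees 0.
#'
#' @param data A [spatial_counts] object.
#' @return A `log_expression` object with `scale_tag = "logCPM"`.
#' @export
compute_logcpm <- function(data) {
  stopifnot(inherits(data, "spatial_counts"))
  y <- log2(sweep(data$counts + 0.5, 1, data$lib_size + 1, "/") * 1e6)
  new_log_expression(y, "logCPM")
}

#' Library-size log-normalized counts
#'
#' Size factor \eqn{f_i = R_i / \bar R}; \eqn{y_{gi} = \log_2(r_{gi}/f_i + 1)}.
#' Used for the mean-logcounts axis of the decile diagnostics, not for
#' weight computation.
#'
#' @param data A [spatial_counts] object.
#' @return A `log_expression` object with `scale_tag = "lognorm"`.
#' @export
lognorm_counts <- function(data) {
  stopifnot(inherits(data, "spatial_counts"))
  if (all(data$lib_size == 0)) stop("all spots empty: cannot normalize")
  f <- data$lib_size / mean(data$lib_size)
  f[f == 0] <- 1  # empty spots contribute log2(0/f + 1) = 0 anyway
  y <- log2(sweep(data$counts, 1, f, "/") + 1)
  new_log_expression(y, "lognorm")
}

#' Scale coordinates jointly into [0, 1]
#'
#' Both axes are shifted to start at 0 and divided by the larger axis range,
#' preserving the aspect ratio, so that a lengthscale of 0.15 on the scaled
#' coordinates means 15% of the maximum width or height of the tissue.
#'
#' @param coords Numeric matrix with two columns.
#' @return Scaled coordinate matrix.
#' @export
scale_coords <- function(coords) {
  coords <- as.matrix(coords)
  rng <- apply(coords, 2, function(v) diff(range(v)))
  ext <- max(rng)
  if (ext <= 0) stop("coordinates span zero extent")
  sweep(coords, 2, apply(coords, 2, min), "-") / ext
}
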