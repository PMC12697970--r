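#' Read and validate a long-format CSV table
#'
#' Reads a comma-separated, UTF-8, headered table and validates it
#' against a named schema of column types, reporting every offending
#' column or duplicated key explicitly.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`).
#' @param key Optional character vector of columns whose combination must
#'   be unique.
#' @return The validated data frame.
#' @export
read_table <- function(path, schema, key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cn in names(schema)) {
    v <- df[[cn]]
    ok <- switch(schema[[cn]],
                 numeric = is.numeric(v),
                 integer = is.numeric(v) && all(v == round(v), na.rm = TRUE),
                 character = is.character(v) || is.factor(v),
                 stop("unknown schema type ", schema[[cn]], call. = FALSE))
    if (!ok)
      stop(sprintf("column '%s' is not of type %s", cn, schema[[cn]]),
           call. = FALSE)
  }
  if (!is.null(key)) {
    kv <- do.call(paste, df[key])
    if (anyDuplicated(kv)) {
      dup <- unique(kv[duplicated(kv)])
      stop(sprintf("duplicate key(s) on (%s): %s",
                   paste(key, collapse = ", "),
                   paste(utils::head(dup, 5), collapse = "; ")),
           call. = FALSE)
    }
  }
  df
}

#' @rdname read_table
#' @export
read_colony_table <- function(path)
  read_table(path, schema = c(experiment = "character", epo = "numeric",
                              ligand = "character", dose = "numeric",
                              replicate = "integer", count = "integer"))

#' @rdname read_table
#' @export
read_subset_table <- function(path)
  read_table(path, schema = c(mouse = "character", treatment = "character",
                              tissue = "character", subset = "character",
                              cells_per_g = "numeric", group = "character"),
             key = c("mouse", "tissue", "subset"))

#' Read an expression matrix with cell metadata
#'
#' Accepts either a MatrixMarket triplet (`matrix.mtx` with sibling
#' `genes.tsv` and `barcodes.tsv`, genes in rows) or a dense CSV (genes in
#' rows, first column gene names, remaining columns cells). The metadata
#' CSV must have a `barcode` column; cells without metadata are an error
#' reporting the count of unmatched barcodes.
#'
#' @param path Path to the `.mtx` or `.csv` matrix file.
#' @param meta_path Path to the metadata CSV.
#' @param genes_path,barcodes_path Overrides for the MTX sibling files.
#' @return A [cell_matrix()].
#' @export
read_expression <- function(path, meta_path, genes_path = NULL,
                            barcodes_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dir, "barcodes.tsv")
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(barcodes_path)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- methods::as(as.matrix(df), "CsparseMatrix")
  } else stop("unsupported matrix format: ", ext, call. = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!"barcode" %in% names(meta))
    stop("metadata must contain a 'barcode' column", call. = FALSE)
  unmatched <- setdiff(colnames(m), meta$barcode)
  if (length(unmatched))
    stop(sprintf("%d cell(s) without metadata (e.g. %s)",
                 length(unmatched), utils::head(unmatched, 3)[1]),
         call. = FALSE)
  meta <- meta[match(colnames(m), meta$barcode), , drop = FALSE]
  rownames(meta) <- meta$barcode
  cell_matrix(m, meta[, setdiff(names(meta), "barcode"), drop = FALSE])
}

#' Write a cell matrix as a MatrixMarket triplet plus metadata CSV
#'
#' @param cm A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_expression <- function(cm, dir) {
  stopifnot(inherits(cm, "cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$genes, file.path(dir, "genes.tsv"))
  writeLines(cm$cells, file.path(dir, "barcodes.tsv"))
  meta <- cbind(barcode = cm$cells, cm$meta)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene names, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' Write a reproducibility manifest for a run
#'
#' Captures the configuration (content-hashed), seed, package version and
#' timestamp of an analysis run as JSON, enabling exact re-execution.
#'
#' @param outdir Output directory.
#' @param config A list of run parameters.
#' @param seed The integer seed used.
#' @return Path of the manifest file, invisibly.
#' @export
run_manifest <- function(outdir, config, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "erythrotune",
    version = as.character(utils::packageVersion("erythrotune")),
    seed = as.integer(seed),
    config = config,
    config_hash = .djb2(cfg_json),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# small dependency-free content hash (djb2 over UTF-8 bytes)
.djb2 <- function(s) {
  b <- utf8ToInt(as.character(s))
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}
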