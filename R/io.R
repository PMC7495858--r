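# Readers and writers: CSV/TSV expression tables, FCS files (read-only),
# sample-level covariate tables, and TSV/JSON exports.

#' Read a cell-by-marker expression matrix
#'
#' Reads CSV/TSV (header row = marker names) or FCS 2.0/3.0/3.1 files into
#' a [marker_matrix()]. An optional arcsinh(x / cofactor) variance-
#' stabilizing transform can be applied (off by default; cofactor 5 is the
#' common CyTOF choice).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"fcs"`.
#' @param channels optional character or integer vector selecting a subset
#'   of markers/channels.
#' @param arcsinh apply `asinh(x / arcsinh_cofactor)`.
#' @param arcsinh_cofactor cofactor for the transform.
#' @param censored mark the result as zero-censored (mass cytometry).
#' @return a `marker_matrix`.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                            channels = NULL, arcsinh = FALSE,
                            arcsinh_cofactor = 5, censored = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", fcs = "fcs",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "fcs") {
    vals <- read_fcs(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop("non-numeric expression column(s): ",
           paste(names(df)[bad], collapse = ", "))
    vals <- as.matrix(df)
  }
  if (!is.null(channels)) vals <- vals[, channels, drop = FALSE]
  if (isTRUE(arcsinh)) vals <- asinh(vals / arcsinh_cofactor)
  marker_matrix(vals, censored = censored)
}

# Minimal FCS 2.0/3.0/3.1 reader: HEADER offsets -> TEXT keyword segment ->
# numeric DATA segment (float, double, or integer; list mode). Channel
# names come from $PnS when present, else $PnN.
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!grepl("^FCS[23]\\.[01]$", version))
    stop(path, ": not a supported FCS file (version field '", version, "')")
  off <- function(i) as.numeric(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8)))
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)

  seek(con, text_beg)
  txt <- readBin(con, "raw", text_end - text_beg + 1)
  delim <- rawToChar(txt[1])
  parts <- strsplit(rawToChar(txt[-1]), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(trimws(parts[seq(2, length(parts), 2)]),
                        toupper(trimws(parts[seq(1, length(parts), 2)])))

  if (data_beg == 0 && !is.na(kw["$BEGINDATA"])) {
    data_beg <- as.numeric(kw["$BEGINDATA"])
    data_end <- as.numeric(kw["$ENDDATA"])
  }
  P <- as.integer(kw["$PAR"]); TOT <- as.integer(kw["$TOT"])
  if (is.na(P) || is.na(TOT)) stop(path, ": FCS file lacks $PAR/$TOT keywords")
  dtype <- toupper(kw["$DATATYPE"])
  byteord <- kw["$BYTEORD"]
  endian <- if (identical(byteord, "4,3,2,1") || identical(byteord, "2,1"))
    "big" else "little"
  bits <- as.integer(kw[paste0("$P", seq_len(P), "B")])
  seek(con, data_beg)
  n_vals <- P * TOT
  vals <- switch(dtype,
    F = readBin(con, "numeric", n_vals, size = 4, endian = endian),
    D = readBin(con, "numeric", n_vals, size = 8, endian = endian),
    I = {
      if (length(unique(bits)) != 1L)
        stop(path, ": mixed-width integer FCS data not supported")
      readBin(con, "integer", n_vals, size = bits[1] / 8, endian = endian,
              signed = bits[1] > 16)
    },
    stop(path, ": unsupported $DATATYPE '", dtype, "'"))
  if (length(vals) < n_vals)
    stop(path, ": DATA segment truncated (expected ", n_vals, " values, got ",
         length(vals), ")")
  m <- matrix(vals, nrow = TOT, ncol = P, byrow = TRUE)
  nm <- vapply(seq_len(P), function(i) {
    s <- kw[paste0("$P", i, "S")]
    if (!is.na(s) && nzchar(s)) s else {
      n <- kw[paste0("$P", i, "N")]
      if (!is.na(n) && nzchar(n)) n else paste0("P", i)
    }
  }, character(1))
  colnames(m) <- nm
  m
}

#' Read covariates and build a design matrix
#'
#' Reads a tabular covariate file (CSV/TSV by extension), dummy-codes the
#' requested categorical columns (first level as reference), and prepends
#' an intercept column. Rows are matched to cells either by an `id_column`
#' against `cell_ids`, or — when the table has one row per cell — by file
#' order. Sample-level tables (one row per sample) are broadcast to cells
#' via `cell_ids`.
#'
#' @param path covariate table file.
#' @param formula_columns character vector of covariate column names to use.
#' @param n_cells number of cells the design must cover (used when matching
#'   by file order).
#' @param id_column optional column of sample/cell identifiers.
#' @param cell_ids optional per-cell identifiers matched against
#'   `id_column`.
#' @return a `design_matrix` with N rows.
#' @export
read_covariates <- function(path, formula_columns, n_cells = NULL,
                            id_column = NULL, cell_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(formula_columns, names(df))
  if (length(missing_cols))
    stop("covariate column(s) not in file: ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(id_column)) {
    if (is.null(cell_ids)) stop("cell_ids required when id_column is given")
    idx <- match(cell_ids, df[[id_column]])
    if (anyNA(idx)) {
      bad <- unique(cell_ids[is.na(idx)])
      stop("unmatched cell IDs (first ", min(10L, length(bad)), "): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    df <- df[idx, , drop = FALSE]
  } else if (!is.null(n_cells) && nrow(df) != n_cells) {
    stop("covariate table has ", nrow(df), " rows but data has ", n_cells,
         " cells; provide id_column/cell_ids to broadcast")
  }
  build_design(df[, formula_columns, drop = FALSE])
}

#' Dummy-code a covariate data frame into a design matrix
#'
#' Character/factor columns are dummy-coded with the first level as
#' reference; numeric columns pass through; an intercept of ones is
#' prepended.
#'
#' @param df data.frame of covariates (one row per cell).
#' @return a `design_matrix`.
#' @export
build_design <- function(df) {
  df <- as.data.frame(df)
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  mm <- stats::model.matrix(~ ., data = df)
  design_matrix(mm, column_names = colnames(mm))
}

#' Write a fit's parameter tables and assignments
#'
#' Writes `means.tsv` (clusters x markers, heatmap-ready), `beta.tsv`,
#' `covariances.tsv` (long format), `assignments.tsv` (per-cell hard label
#' plus responsibilities), `proportions.tsv` (per covariate pattern), and
#' a JSON `manifest.json` capturing version, seed, and options so the run
#' is reproducible.
#'
#' @param fit a `cytomix_fit`.
#' @param X the design matrix used in the fit.
#' @param dir output directory (created if needed).
#' @param options list of run options recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, X, dir, options = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- ncol(fit$params$mu)
  mu_t <- t(fit$params$mu)
  rn <- paste0("cluster", seq_len(L))
  utils::write.table(data.frame(cluster = rn, mu_t, check.names = FALSE),
                     file.path(dir, "means.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(coef = rownames(fit$params$beta) %||%
                                  paste0("b", seq_len(nrow(fit$params$beta))),
                                fit$params$beta, check.names = FALSE),
                     file.path(dir, "beta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cov_long <- do.call(rbind, lapply(seq_len(L), function(l) {
    s <- fit$params$sigma[[l]]
    data.frame(cluster = l, row = rep(seq_len(nrow(s)), ncol(s)),
               col = rep(seq_len(ncol(s)), each = nrow(s)),
               value = as.vector(s))
  }))
  utils::write.table(cov_long, file.path(dir, "covariances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = seq_len(nrow(fit$w)),
                                cluster = hard_labels(fit), fit$w,
                                check.names = FALSE),
                     file.path(dir, "assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  props <- category_proportions(fit, X)
  utils::write.table(data.frame(pattern = seq_len(nrow(props)), props,
                                check.names = FALSE),
                     file.path(dir, "proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(package = "cytomix",
                   version = as.character(utils::packageVersion("cytomix")),
                   model = fit$model, seed = fit$seed, n_iter = fit$n_iter,
                   converged = fit$converged, loglik = fit$loglik,
                   options = options)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
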