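#' Read a wide protein-by-sample abundance TSV
#'
#' Canonical input: tab-separated, one row per protein; the first column is
#' the protein id, an optional second column `gene_symbol` carries symbols,
#' remaining columns are samples. Empty cells, `NA` and `NaN` are missing;
#' by TMT convention a literal `0` is also treated as missing
#' (`zero_as_missing = TRUE`, the default), since a zero reporter-ion
#' intensity means the protein was not measured in that channel.
#'
#' @param path File path.
#' @param zero_as_missing Convert zeros to missing (default `TRUE`).
#' @param scale Scale state to stamp on the matrix (default `"raw"`).
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, zero_as_missing = TRUE, scale = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "NaN"))
  if (ncol(df) < 2) stop("abundance file needs an id column and >= 1 sample")
  has_symbols <- identical(names(df)[2], "gene_symbol")
  ids <- as.character(df[[1]])
  syms <- if (has_symbols) as.character(df[[2]]) else ids
  first_sample <- if (has_symbols) 3L else 2L
  sample_names <- names(df)[first_sample:ncol(df)]
  if (anyDuplicated(sample_names))
    stop("duplicate sample column(s): ",
         paste(unique(sample_names[duplicated(sample_names)]),
               collapse = ", "))
  vals <- df[, first_sample:ncol(df), drop = FALSE]
  names(vals) <- sample_names
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) &
                     is.na(suppressWarnings(as.numeric(vals[[j]]))))
      if (length(bad))
        stop(sprintf("non-numeric value at row %d, column '%s'",
                     bad[1], names(vals)[j]))
      vals[[j]] <- as.numeric(vals[[j]])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (zero_as_missing) m[!is.na(m) & m == 0] <- NA_real_
  abundance_matrix(m, syms, scale = scale)
}

#' Write an abundance matrix as wide TSV
#'
#' Full-precision round-trip companion to [read_abundance()]: values are
#' written with 17 significant digits and missing cells as empty fields.
#'
#' @param matrix An [abundance_matrix()].
#' @param path Output file path.
#' @export
write_abundance <- function(matrix, path) {
  stopifnot(is_abundance_matrix(matrix))
  v <- matrix$values
  df <- data.frame(protein_id = rownames(v),
                   gene_symbol = unname(matrix$gene_symbols[rownames(v)]),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in colnames(v)) df[[j]] <- v[, j]
  write_tsv(df, path)
  invisible(path)
}

# deterministic full-precision TSV writer shared by all result tables
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    x <- sprintf("%.17g", df[[j]])
    x[is.na(df[[j]])] <- ""
    df[[j]] <- x
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then members.
#' Duplicate members within a set are collapsed; duplicate set names are an
#' error by default (or suffixed `.1`, `.2`, ... with
#' `on_duplicate = "suffix"`).
#'
#' @param path File path.
#' @param on_duplicate `"error"` (default) or `"suffix"`.
#' @return A named list of character vectors with a `description`
#'   attribute; no set is empty.
#' @export
read_gmt <- function(path, on_duplicate = c("error", "suffix")) {
  on_duplicate <- match.arg(on_duplicate)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    nm <- f[1]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT set '", nm, "' is empty")
    if (nm %in% names(sets)) {
      if (on_duplicate == "error") stop("duplicate GMT set name: ", nm)
      k <- sum(startsWith(names(sets), nm))
      nm <- paste0(nm, ".", k)
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Default pipeline configuration
#'
#' All stage thresholds in one place: the missingness cut (drop proteins
#' more than 50% missing), AT+ ratio cutoff 0.226 with MoCA 24/24, FDR
#' levels for volcano/heatmap reporting, the strict meta-p ROC eligibility
#' cut 1e-4, kME assignment cutoff 0.30, enrichment Z cutoff 1.96 with
#' minimum 5 genes per set, bootstrap count, polish tolerance, panel size,
#' and the run seed.
#'
#' The default regression path removes batch only (the primary analysis);
#' set `covariates = c("age", "sex", "race", "batch")` for the demographic
#' sensitivity path. Regressing fitted demographic effects out of small
#' cohorts and re-testing the residuals is mildly anticonservative, which
#' is why it is the sensitivity rather than the primary path.
#'
#' @param ... Named overrides of any default.
#' @return A named list (class `hepplasma_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    max_missing_frac = 0.5,
    use_gis = TRUE,
    polish_tol = 1e-6,
    polish_max_iter = 100L,
    covariates = "batch",
    protected = "diagnosis",
    bootstrap_B = 200L,
    fdr_volcano = 0.05,
    fdr_heatmap = 5e-4,
    at_ratio_cut = 0.226,
    at_moca_ad = 24,
    at_moca_ctl = 24,
    meta_p_max = 1e-4,
    kme_min = 0.30,
    z_cut = 1.96,
    min_genes = 5,
    panel_size = 5L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$max_missing_frac >= 0, cfg$max_missing_frac <= 1,
            cfg$meta_p_max > 0, cfg$kme_min >= -1, cfg$kme_min <= 1,
            cfg$min_genes >= 1, cfg$bootstrap_B >= 1)
  structure(cfg, class = "hepplasma_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips [default_config()] objects; unknown keys error.
#'
#' @param path YAML file path.
#' @return For `read_config`, a config list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config A config list from [default_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
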