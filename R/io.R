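# Readers and writers for the package's single TSV dialect: tab-separated,
# '.' decimal mark, one header row, '#'-prefixed comment lines.

#' Read per-SNP summary statistics from a TSV file
#'
#' Auto-detects one of two schemas from the header: allele counts
#' (`snp_id`, `n00`, `n01`, `n10`, `n11`) or precomputed summaries
#' (`snp_id`, `mu_hat`, `se`).  Lines starting with `#` are comments.
#' Count tables are validated ([allele_counts()] invariants) and returned
#' as count data frames; summary files are validated (`se > 0`) and get a
#' `z` column.  Malformed rows are reported with their line number.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` in one of the two schemas, with attribute
#'   `schema` set to `"counts"` or `"summary"`.
#' @export
read_summary_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0L) stop("no data in ", path, call. = FALSE)
  df <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE, dec = ".")
  line_no <- which(keep)[-1L]  # file line of each data row

  counts_cols <- c("snp_id", "n00", "n01", "n10", "n11")
  summary_cols <- c("snp_id", "mu_hat", "se")
  has_counts <- all(counts_cols %in% names(df))
  has_summary <- all(c("mu_hat", "se") %in% names(df))
  if (has_counts && has_summary) {
    stop("mixed schemas in ", path,
         ": both count and summary columns present", call. = FALSE)
  }
  if (has_counts) {
    cells <- as.matrix(df[, c("n00", "n01", "n10", "n11")])
    bad <- rowSums(!is.finite(cells) | cells < 0 |
                   cells != round(cells)) > 0
    bad <- bad | (df$n00 + df$n01) %% 2 != 0 | (df$n10 + df$n11) %% 2 != 0
    if (any(bad)) {
      stop("invalid allele counts at line(s) ",
           paste(utils::head(line_no[bad], 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    out <- allele_counts(df$n00, df$n01, df$n10, df$n11, snp_id = df$snp_id)
    attr(out, "schema") <- "counts"
    return(out)
  }
  if (has_summary) {
    bad <- !is.finite(df$mu_hat) | !is.finite(df$se) | df$se <= 0
    if (any(bad)) {
      stop("invalid summary row(s) at line(s) ",
           paste(utils::head(line_no[bad], 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    if (!"snp_id" %in% names(df)) df$snp_id <- paste0("snp", seq_len(nrow(df)))
    out <- data.frame(snp_id = as.character(df$snp_id), mu_hat = df$mu_hat,
                      se = df$se, z = df$mu_hat / df$se,
                      stringsAsFactors = FALSE)
    attr(out, "schema") <- "summary"
    return(out)
  }
  stop("unrecognised header in ", path, "; expected columns ",
       paste(counts_cols, collapse = ","), " or ",
       paste(summary_cols, collapse = ","), call. = FALSE)
}

# Coerce either schema to the summary record used by the estimators.
as_summary_records <- function(x, zero_cell_correction = TRUE) {
  if (identical(attr(x, "schema"), "counts") ||
      all(c("n00", "n01", "n10", "n11") %in% names(x))) {
    wald_summary(x, zero_cell_correction = zero_cell_correction)
  } else {
    as_assoc_summary(x)
  }
}

#' Write a results table as TSV with a provenance header
#'
#' Writes `#`-prefixed comment lines carrying the package version, seed
#' and any options, then the records tab-separated.  Floating-point
#' columns are written with 6 significant digits, so output is
#' reproducible across runs and round-trips through [read_summary_tsv()]
#' (up to that precision).
#'
#' @param records A data frame.
#' @param path Output path.
#' @param seed Seed to record in the header (or `NULL`).
#' @param options Named list of options to record in the header.
#' @export
write_results_tsv <- function(records, path, seed = NULL, options = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# repower %s", as.character(packageVersion("repower"))),
             con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  for (nm in names(options)) {
    writeLines(sprintf("# %s=%s", nm, format(options[[nm]])), con)
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read/write the fitted prior as a flat key=value file
#'
#' Two lines, `pi0=<value>` and `sigma0_sq=<value>` (`Inf` allowed),
#' consumed by the power-estimation and design commands.
#'
#' @param prior A [mixture_prior()].
#' @param path File path.
#' @return `write_prior_file()` returns the path invisibly;
#'   `read_prior_file()` returns a [mixture_prior()].
#' @export
write_prior_file <- function(prior, path) {
  stopifnot(inherits(prior, "mixture_prior"))
  writeLines(c(sprintf("pi0=%.17g", prior$pi0),
               sprintf("sigma0_sq=%.17g", prior$sigma0_sq)), path)
  invisible(path)
}

#' @rdname write_prior_file
#' @export
read_prior_file <- function(path) {
  kv <- read_key_value(path)
  if (!all(c("pi0", "sigma0_sq") %in% names(kv))) {
    stop("prior file must define pi0 and sigma0_sq", call. = FALSE)
  }
  mixture_prior(as.numeric(kv[["pi0"]]), as.numeric(kv[["sigma0_sq"]]))
}

# Flat key=value reader shared by the prior file and CLI config files.
read_key_value <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop("malformed key=value line(s) in ", path, ": ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  stats::setNames(vapply(kv, `[`, character(1), 3L),
                  vapply(kv, `[`, character(1), 2L))
}
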