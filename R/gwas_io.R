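#' @keywords internal
.sumstats_cols <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

# Common header spellings seen in IEU / consortium exports, used when the
# caller supplies no explicit column_map.
.default_aliases <- list(
  snp_id        = c("snp_id", "snp", "rsid", "rs_id", "variant_id", "markername", "id"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt"),
  other_allele  = c("other_allele", "oa", "nea", "a2", "allele2", "ref"),
  eaf           = c("eaf", "af", "freq", "effect_allele_frequency", "maf"),
  beta          = c("beta", "b", "effect", "beta_hat"),
  se            = c("se", "standard_error", "stderr"),
  pval          = c("pval", "p", "p_value", "pvalue", "p.value"),
  n             = c("n", "samplesize", "sample_size", "n_total")
)

#' Construct a validated summary-statistics tibble
#'
#' Coerces a data frame of per-SNP GWAS associations into the validated
#' `mr_sumstats` form used throughout the package. Rows violating per-record
#' invariants (allele codes outside A/C/G/T, identical alleles, `eaf` outside
#' \[0, 1\], non-positive `se`, `pval` outside (0, 1\], non-positive `n`, or a
#' duplicated `snp_id`) are dropped with a warning that counts them; `eaf` may
#' be `NA` (frequency-less panels), in which case palindromic variants cannot
#' be oriented during harmonization and are dropped there.
#'
#' @param x A data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   Positions are 1-based base-pair coordinates; `beta` is the per-allele
#'   effect of `effect_allele` (log-odds for binary traits, standardized
#'   units for quantitative traits).
#' @param trait_label Free-text trait name carried as metadata.
#' @param trait_type `"quantitative"` or `"binary"`; controls whether report
#'   rows label exponentiated effects as odds ratios.
#' @param quiet Suppress the dropped-row warning.
#' @return A tibble of class `mr_sumstats` with attributes `trait_label`,
#'   `trait_type` and `n_dropped`.
#' @examples
#' ss <- as_sumstats(example_sumstats(), trait_label = "toy exposure")
#' attr(ss, "trait_label")
#' @export
as_sumstats <- function(x, trait_label = "trait",
                        trait_type = c("quantitative", "binary"),
                        quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  missing_cols <- setdiff(.sumstats_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "summary statistics are missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- dplyr::select(x, dplyr::all_of(.sumstats_cols))
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.numeric(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) x[[col]] <- as.numeric(x[[col]])

  ok <- !is.na(x$snp_id) & nzchar(x$snp_id) &
    x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    !is.na(x$beta) & is.finite(x$beta) &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$pval) & x$pval > 0 & x$pval <= 1 &
    !is.na(x$n) & x$n > 0 &
    !is.na(x$pos) & x$pos >= 1
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(x$snp_id)
  keep <- ok & !dup
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    warn(sprintf(
      "as_sumstats(): dropped %d of %d row(s) failing record invariants (%d invalid, %d duplicate snp_id)",
      n_dropped, nrow(x), sum(!ok), sum(dup & ok)
    ))
  }
  out <- x[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no valid summary-statistics rows remain after validation")
  }
  structure(
    out,
    trait_label = trait_label,
    trait_type = trait_type,
    n_dropped = n_dropped,
    class = c("mr_sumstats", class(out))
  )
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited text file (auto-detected from the header
#' line) with one row per variant, resolves column names through `column_map`
#' and the built-in alias list, and validates it via [as_sumstats()]. Lines
#' beginning with `#` are treated as comments; `write_sumstats()` uses them to
#' store the trait label and type, which are recovered here unless overridden.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names.
#' @param trait_type,trait_label Metadata; defaults come from the file header
#'   comments when present, otherwise `"quantitative"` / the file name.
#' @inheritParams as_sumstats
#' @return An `mr_sumstats` tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_type = NULL,
                          trait_label = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path, n_max = 50L)
  meta <- .parse_header_meta(lines)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header) || !nzchar(header)) abort("file has no header row")
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
  names(raw) <- tolower(names(raw))
  for (canon in .sumstats_cols) {
    src <- if (canon %in% names(column_map)) column_map[[canon]] else NULL
    if (!is.null(src)) {
      if (!tolower(src) %in% names(raw)) {
        abort(sprintf("mapped column '%s' (for '%s') not found in file", src, canon))
      }
      names(raw)[names(raw) == tolower(src)] <- canon
    } else if (!canon %in% names(raw)) {
      hit <- intersect(.default_aliases[[canon]], names(raw))
      if (length(hit) > 0) names(raw)[names(raw) == hit[1]] <- canon
    }
  }
  missing_cols <- setdiff(.sumstats_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "required column(s) not resolvable from header: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  as_sumstats(
    raw,
    trait_label = trait_label %||% meta$trait_label %||% basename(path),
    trait_type = trait_type %||% meta$trait_type %||% "quantitative",
    quiet = quiet
  )
}

.parse_header_meta <- function(lines) {
  meta <- list()
  for (ln in lines[startsWith(lines, "#")]) {
    m <- regmatches(ln, regexec("^#\\s*(trait_label|trait_type)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' Write a summary-statistics table
#'
#' Writes tab-delimited text with two leading comment lines recording the
#' trait label and type, so that `read_sumstats(write_sumstats(s))`
#' reproduces `s` field-for-field (numeric fields use shortest round-trip
#' representation).
#'
#' @param stats An `mr_sumstats` tibble (or plain data frame with the
#'   required columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  if (nrow(stats) == 0) abort("refusing to write an empty summary-statistics table")
  label <- attr(stats, "trait_label") %||% "trait"
  type <- attr(stats, "trait_type") %||% "quantitative"
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(c(
    paste0("# trait_label: ", label),
    paste0("# trait_type: ", type)
  ), con)
  close(con)
  readr::write_tsv(as_tibble(stats)[.sumstats_cols], path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Pairwise linkage-disequilibrium lookup
#'
#' A symmetric r-squared lookup over SNP pairs, with unlisted pairs returning
#' `default_r2` (0: treated as independent, so clumping binds only through
#' listed pairs) and `r2(a, a) = 1`.
#'
#' @param pairs A data frame with columns `snp_a`, `snp_b`, `r2`, or `NULL`
#'   for an empty (all-independent) table.
#' @param default_r2 Value returned for unlisted pairs.
#' @return An object of class `mr_ld`.
#' @export
ld_info <- function(pairs = NULL, default_r2 = 0) {
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0) {
    pairs <- tibble(snp_a = character(), snp_b = character(), r2 = numeric())
  }
  pairs <- as_tibble(pairs)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(pairs))) {
    abort("LD pairs need columns snp_a, snp_b, r2")
  }
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
    abort("LD r2 values must lie in [0, 1]")
  }
  key <- paste(pmin(pairs$snp_a, pairs$snp_b), pmax(pairs$snp_a, pairs$snp_b), sep = "\r")
  lookup <- stats::setNames(pairs$r2, key)
  structure(
    list(pairs = pairs[need], lookup = lookup, default_r2 = default_r2),
    class = "mr_ld"
  )
}

#' Read a pairwise-LD triplet file
#'
#' Long-format delimited text with columns `snp_a`, `snp_b`, `r2`. An empty
#' file yields an all-independent lookup.
#'
#' @param path File path.
#' @param default_r2 Value assumed for unlisted pairs.
#' @return An `mr_ld` object.
#' @export
read_ld <- function(path, default_r2 = 0) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(ld_info(NULL, default_r2 = default_r2))
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  raw <- readr::read_delim(
    I(paste(lines, collapse = "\n")), delim = delim,
    show_col_types = FALSE, progress = FALSE, trim_ws = TRUE
  )
  names(raw) <- tolower(names(raw))
  ld_info(raw, default_r2 = default_r2)
}

#' Query pairwise r-squared
#'
#' @param ld An `mr_ld` object.
#' @param snp_a,snp_b Character vectors of SNP ids (recycled to common
#'   length).
#' @return Numeric vector of r-squared values; `1` on the diagonal,
#'   `default_r2` for unlisted pairs, symmetric in its arguments.
#' @export
ld_r2 <- function(ld, snp_a, snp_b) {
  stopifnot(inherits(ld, "mr_ld"))
  n <- max(length(snp_a), length(snp_b))
  snp_a <- rep_len(as.character(snp_a), n)
  snp_b <- rep_len(as.character(snp_b), n)
  key <- paste(pmin(snp_a, snp_b), pmax(snp_a, snp_b), sep = "\r")
  out <- unname(ld$lookup[key])
  out[is.na(out)] <- ld$default_r2
  out[snp_a == snp_b] <- 1
  out
}

#' @export
print.mr_ld <- function(x, ...) {
  cat(sprintf(
    "<mr_ld> %d listed pair(s), default r2 = %g\n",
    nrow(x$pairs), x$default_r2
  ))
  invisible(x)
}

#' A tiny well-formed summary-statistics table
#'
#' Two variants with valid fields, used in examples.
#'
#' @return A plain tibble suitable for [as_sumstats()].
#' @export
example_sumstats <- function() {
  tibble(
    snp_id = c("rs1", "rs2"),
    chrom = c("1", "2"),
    pos = c(1e6, 2e6),
    effect_allele = c("A", "C"),
    other_allele = c("G", "T"),
    eaf = c(0.25, 0.40),
    beta = c(0.10, -0.05),
    se = c(0.01, 0.02),
    pval = c(1e-10, 1.2e-2),
    n = c(18340, 18340)
  )
}
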