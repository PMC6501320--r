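#' @keywords internal
#' Required column sets for each tabular format.
.variant_cols <- c("sample_id", "gene", "transcript", "exon", "cdna_change",
                   "protein_change", "functional_class", "splice_distance",
                   "read_depth", "variant_quality", "genotype_quality",
                   "allelic_ratio", "is_last_exon")
.subject_cols <- c("subject_id", "status", "age", "er_status", "grade",
                   "fh_first_degree", "fh_any")
.clinvar_cols <- c("gene", "transcript", "cdna_change", "label")
.external_cols <- c("cohort_name", "n_total", "gene", "carrier_count")

.check_header <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error in ", what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Strict numeric parsing: "" / NA -> NA, anything unparseable -> error with
# the 1-based data line number (header is line 0).
.parse_num <- function(x, col, integer = FALSE) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("format error: unparseable numeric in column '", col,
         "' at data line ", bad[1], " (value '", x[bad[1]], "')",
         call. = FALSE)
  if (integer) {
    frac <- which(!is.na(out) & out != floor(out))
    if (length(frac))
      stop("format error: non-integer value in column '", col,
           "' at data line ", frac[1], call. = FALSE)
    out <- as.integer(out)
  }
  out
}

.parse_logical <- function(x, col) {
  x <- toupper(trimws(as.character(x)))
  x[x == "" | x == "NA"] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("format error: unparseable logical in column '", col,
         "' at data line ", bad[1], call. = FALSE)
  out
}

.parse_enum <- function(x, levels, col, allow_na = FALSE) {
  x <- tolower(trimws(as.character(x)))
  x[x == "" | x == "na"] <- NA_character_
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad))
    stop("format error: invalid value '", x[bad[1]], "' in column '", col,
         "' at data line ", bad[1], "; expected one of: ",
         paste(levels, collapse = ", "), call. = FALSE)
  if (!allow_na && anyNA(x))
    stop("format error: missing value in required column '", col, "'",
         call. = FALSE)
  x
}

#' Normalize a variant key for ClinVar matching
#'
#' Builds the join key used to look annotated calls up in the ClinVar-style
#' table: gene and transcript are upper-cased and stripped of whitespace, the
#' HGVS cDNA string is stripped of whitespace, its leading `c.` prefix is
#' canonicalized, and the remainder is upper-cased so that del/dup/ins
#' spellings match case-insensitively.
#'
#' @param gene,transcript,cdna_change Character vectors (recycled together).
#' @return Character vector of normalized keys.
#' @examples
#' normalize_variant_key("chek2", "NM_007194", " C.1100DELC ")
#' @export
normalize_variant_key <- function(gene, transcript, cdna_change) {
  if (length(gene) == 0 && length(transcript) == 0 && length(cdna_change) == 0)
    return(character(0))  # paste() would recycle zero-length args to ""
  g <- toupper(gsub("[[:space:]]", "", as.character(gene)))
  t <- toupper(gsub("[[:space:]]", "", as.character(transcript)))
  c_ <- gsub("[[:space:]]", "", as.character(cdna_change))
  c_ <- sub("^[cC]\\.", "", c_)
  paste(g, t, paste0("c.", toupper(c_)), sep = "|")
}

#' Read an annotated variant call table
#'
#' Reads the per-sample variant TSV (one row per sample x variant, Annovar-style
#' annotation plus QC metrics), validates every field, and rejects rows whose
#' gene is not on the configured panel. Rejected rows are reported via a
#' message and attached as the `"rejected"` attribute; malformed numerics and
#' invariant violations (e.g. an allelic ratio outside [0, 1]) are row-level
#' errors, never silent coercions.
#'
#' @param path Path to a tab-separated file with header columns `sample_id`,
#'   `gene`, `transcript`, `exon`, `cdna_change`, `protein_change`,
#'   `functional_class`, `splice_distance`, `read_depth`, `variant_quality`,
#'   `genotype_quality`, `allelic_ratio`, `is_last_exon`.
#' @param config A [burden_config()]; supplies the gene panel.
#' @return A validated `data.frame` of variant calls with attribute
#'   `"rejected"` (a data.frame of off-panel rows with a `reject_reason`
#'   column) and `"n_read"` (total data rows in the file).
#' @export
read_variant_table <- function(path, config = burden_config()) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  .check_header(raw, .variant_cols, basename(path))
  validate_variants(raw, config, what = basename(path))
}

#' Validate a raw variant call data.frame
#'
#' The in-memory counterpart of [read_variant_table()]; used by the reader,
#' the pipeline and tests.
#'
#' @param raw A data.frame with the variant table columns (character or typed).
#' @param config A [burden_config()].
#' @param what Label used in messages.
#' @return As [read_variant_table()].
#' @export
validate_variants <- function(raw, config = burden_config(), what = "variants") {
  .check_header(raw, .variant_cols, what)
  n_read <- nrow(raw)
  df <- data.frame(
    sample_id = trimws(as.character(raw$sample_id)),
    gene = toupper(trimws(as.character(raw$gene))),
    transcript = trimws(as.character(raw$transcript)),
    exon = .parse_num(raw$exon, "exon", integer = TRUE),
    cdna_change = trimws(as.character(raw$cdna_change)),
    protein_change = trimws(as.character(raw$protein_change)),
    functional_class = .parse_enum(raw$functional_class, functional_classes(),
                                   "functional_class"),
    splice_distance = .parse_num(raw$splice_distance, "splice_distance",
                                 integer = TRUE),
    read_depth = .parse_num(raw$read_depth, "read_depth"),
    variant_quality = .parse_num(raw$variant_quality, "variant_quality"),
    genotype_quality = .parse_num(raw$genotype_quality, "genotype_quality"),
    allelic_ratio = .parse_num(raw$allelic_ratio, "allelic_ratio"),
    is_last_exon = .parse_logical(raw$is_last_exon, "is_last_exon"),
    stringsAsFactors = FALSE
  )
  df$protein_change[!is.na(df$protein_change) &
                      df$protein_change == ""] <- NA_character_
  if (anyNA(df$sample_id) || any(df$sample_id == ""))
    stop("format error: empty sample_id", call. = FALSE)

  bad_ar <- which(!is.na(df$allelic_ratio) &
                    (df$allelic_ratio < 0 | df$allelic_ratio > 1))
  if (length(bad_ar))
    stop("format error: allelic_ratio outside [0, 1] at data line ", bad_ar[1],
         " (value ", df$allelic_ratio[bad_ar[1]], ")", call. = FALSE)
  for (col in c("read_depth", "variant_quality", "genotype_quality")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop("format error: negative ", col, " at data line ", bad[1],
           call. = FALSE)
  }
  bad_exon <- which(!is.na(df$exon) & df$exon < 1)
  if (length(bad_exon))
    stop("format error: exon must be a positive integer (data line ",
         bad_exon[1], ")", call. = FALSE)

  # splice_distance present <=> intronic
  intr <- df$functional_class == "intronic"
  bad_sd <- which(intr & is.na(df$splice_distance))
  if (length(bad_sd))
    stop("format error: intronic call missing splice_distance at data line ",
         bad_sd[1], call. = FALSE)
  bad_sd2 <- which(!intr & !is.na(df$splice_distance))
  if (length(bad_sd2))
    stop("format error: splice_distance given for non-intronic call at data line ",
         bad_sd2[1], call. = FALSE)

  off_panel <- !(df$gene %in% config$panel_genes)
  rejected <- df[off_panel, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reject_reason <- "gene not on panel"
    message(nrow(rejected), " row(s) rejected from ", what,
            ": gene not on panel")
  } else {
    rejected$reject_reason <- character(0)
  }
  df <- df[!off_panel, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, rejected = rejected, n_read = n_read)
}

#' Derive the age group used by the stratified analyses
#'
#' @param age Numeric age in years (NA allowed).
#' @return Character: `"under40"` (age < 40), `"40to49"` (40 <= age < 50),
#'   otherwise `"other"` (including missing age).
#' @export
age_group <- function(age) {
  out <- rep("other", length(age))
  out[!is.na(age) & age < 40] <- "under40"
  out[!is.na(age) & age >= 40 & age < 50] <- "40to49"
  out
}

#' Read the subject phenotype table
#'
#' Reads the case/control phenotype CSV, validates the enums, derives the
#' `age_group` stratum and enforces the family-history consistency rule
#' (a first-degree family history implies a family history in any relative).
#'
#' @param path Path to a CSV with columns `subject_id`, `status`, `age`,
#'   `er_status`, `grade`, `fh_first_degree`, `fh_any`.
#' @return A validated `data.frame` of subjects with an added `age_group`
#'   column; attribute `"n_read"` records the raw row count.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  .check_header(raw, .subject_cols, basename(path))
  validate_subjects(raw, what = basename(path))
}

#' @rdname read_subjects
#' @param raw A data.frame with the subject columns.
#' @param what Label used in error messages.
#' @export
validate_subjects <- function(raw, what = "subjects") {
  .check_header(raw, .subject_cols, what)
  df <- data.frame(
    subject_id = trimws(as.character(raw$subject_id)),
    status = .parse_enum(raw$status, c("case", "control"), "status"),
    age = .parse_num(raw$age, "age"),
    er_status = .parse_enum(raw$er_status, c("positive", "negative", "unknown"),
                            "er_status"),
    grade = .parse_enum(raw$grade, c("high", "intermediate", "low", "unknown"),
                        "grade"),
    fh_first_degree = .parse_enum(raw$fh_first_degree,
                                  c("yes", "no", "unknown"), "fh_first_degree"),
    fh_any = .parse_enum(raw$fh_any, c("yes", "no", "unknown"), "fh_any"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$subject_id))
    stop("format error: duplicated subject_id in ", what, call. = FALSE)
  bad_fh <- which(df$fh_first_degree == "yes" & df$fh_any != "yes")
  if (length(bad_fh))
    stop("format error: fh_first_degree = yes requires fh_any = yes ",
         "(data line ", bad_fh[1], ")", call. = FALSE)
  df$age_group <- age_group(df$age)
  rownames(df) <- NULL
  structure(df, n_read = nrow(raw))
}

#' Read a ClinVar-style lookup table
#'
#' Reads the variant-to-clinical-label lookup (already collapsed to one label
#' per variant) and indexes it by normalized variant key. Duplicate keys after
#' normalization are an error.
#'
#' @param path Path to a TSV with columns `gene`, `transcript`, `cdna_change`,
#'   `label` (label one of benign / vus / conflicting / pathogenic).
#' @return A `data.frame` of class `clinvar_table` with an added `key` column.
#' @export
read_clinvar <- function(path) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  .check_header(raw, .clinvar_cols, basename(path))
  validate_clinvar(raw)
}

#' @rdname read_clinvar
#' @param raw A data.frame with the ClinVar columns.
#' @export
validate_clinvar <- function(raw) {
  .check_header(raw, .clinvar_cols, "clinvar")
  df <- data.frame(
    gene = toupper(trimws(as.character(raw$gene))),
    transcript = trimws(as.character(raw$transcript)),
    cdna_change = trimws(as.character(raw$cdna_change)),
    label = .parse_enum(raw$label, clinvar_labels(), "label"),
    stringsAsFactors = FALSE
  )
  df$key <- normalize_variant_key(df$gene, df$transcript, df$cdna_change)
  dup <- duplicated(df$key)
  if (any(dup))
    stop("format error: duplicate ClinVar key after normalization: ",
         df$key[which(dup)[1]], call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("clinvar_table", "data.frame")
  df
}

#' Read an external-control carrier-count table
#'
#' Reads gnomAD-style per-gene carrier counts for a replication control
#' cohort. All rows must share one cohort name and total size, and every
#' per-gene carrier count must not exceed the cohort size.
#'
#' @param path Path to a TSV with columns `cohort_name`, `n_total`, `gene`,
#'   `carrier_count`.
#' @return An object of class `external_controls`: a list with elements
#'   `cohort_name`, `n_total` and `carriers` (named integer vector by gene).
#' @export
read_external_controls <- function(path) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  .check_header(raw, .external_cols, basename(path))
  validate_external_controls(raw)
}

#' @rdname read_external_controls
#' @param raw A data.frame with the external-control columns.
#' @export
validate_external_controls <- function(raw) {
  .check_header(raw, .external_cols, "external controls")
  cohort <- unique(trimws(as.character(raw$cohort_name)))
  if (length(cohort) != 1)
    stop("format error: external-control table must describe one cohort",
         call. = FALSE)
  n_total <- unique(.parse_num(raw$n_total, "n_total", integer = TRUE))
  if (length(n_total) != 1 || is.na(n_total) || n_total < 1)
    stop("format error: n_total must be a single positive integer",
         call. = FALSE)
  genes <- toupper(trimws(as.character(raw$gene)))
  if (anyDuplicated(genes))
    stop("format error: duplicated gene in external-control table",
         call. = FALSE)
  counts <- .parse_num(raw$carrier_count, "carrier_count", integer = TRUE)
  if (anyNA(counts) || any(counts < 0))
    stop("format error: carrier_count must be non-negative", call. = FALSE)
  if (any(counts > n_total))
    stop("format error: carrier_count exceeds n_total for gene ",
         genes[which(counts > n_total)[1]], call. = FALSE)
  structure(list(cohort_name = cohort, n_total = n_total,
                 carriers = stats::setNames(counts, genes)),
            class = "external_controls")
}

#' @export
print.external_controls <- function(x, ...) {
  cat("External control cohort:", x$cohort_name,
      sprintf("(N = %d)\n", x$n_total))
  print(x$carriers)
  invisible(x)
}

#' Write pipeline tables
#'
#' Writers matching the readers: variants, ClinVar and external-control tables
#' as TSV, subjects as CSV. Reading a written table back reproduces the
#' validated input field for field.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x[, .variant_cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variant_table
#' @export
write_subjects <- function(x, path) {
  utils::write.csv(x[, .subject_cols, drop = FALSE], path,
                   quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variant_table
#' @export
write_clinvar <- function(x, path) {
  utils::write.table(as.data.frame(x)[, .clinvar_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variant_table
#' @export
write_external_controls <- function(x, path) {
  df <- data.frame(cohort_name = x$cohort_name, n_total = x$n_total,
                   gene = names(x$carriers),
                   carrier_count = unname(x$carriers))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
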