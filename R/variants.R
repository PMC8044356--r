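#' Construct a validated table of somatic variant calls
#'
#' A variant-call table is an ordinary data frame with one row per annotated
#' somatic call and the columns `sample_id`, `gene`, `chrom`, `pos`, `ref`,
#' `alt`, `vaf`, `pop_freq_max`, `effect`, `hotspot` (and optionally
#' `timepoint`). `vaf` is the variant allele fraction in \[0, 1\];
#' `pop_freq_max` is the maximum allele frequency observed across population
#' databases, `NA` when the variant is absent from all of them; `effect` is
#' one of [effect_levels()]; `hotspot` flags membership in a cancer-hotspot
#' catalogue (supplied upstream, never computed here).
#'
#' @param sample_id,gene,chrom,ref,alt Character vectors, recycled to a
#'   common length.
#' @param pos 1-based integer genomic positions (`pos >= 1`).
#' @param vaf Numeric variant allele fractions in \[0, 1\].
#' @param pop_freq_max Numeric fractions in \[0, 1\], `NA` allowed.
#' @param effect Character vector of effect classes, see [effect_levels()].
#' @param hotspot Logical hotspot flags.
#' @param timepoint Optional character vector, `"pre_nac"` or `"post_nac"`.
#'
#' @return A `data.frame` with class `variant_calls` prepended.
#' @examples
#' variant_calls(sample_id = "S1", gene = "TP53", chrom = "17", pos = 7578406,
#'               ref = "C", alt = "T", vaf = 0.31, pop_freq_max = 0,
#'               effect = "nonsynonymous_snv", hotspot = TRUE)
#' @export
variant_calls <- function(sample_id = character(), gene = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          vaf = numeric(), pop_freq_max = numeric(),
                          effect = character(), hotspot = logical(),
                          timepoint = NULL) {
  df <- data.frame(
    sample_id = as.character(sample_id), gene = as.character(gene),
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    vaf = as.numeric(vaf), pop_freq_max = as.numeric(pop_freq_max),
    effect = as.character(effect), hotspot = as.logical(hotspot),
    stringsAsFactors = FALSE
  )
  if (!is.null(timepoint)) df$timepoint <- as.character(timepoint)
  validate_variant_calls(df)
}

#' Validate a variant-call table against its invariants
#'
#' Checks `0 <= vaf <= 1`, `pos >= 1`, `ref != alt`, recognised `effect`
#' labels and fractional `pop_freq_max`. Called by every constructor and
#' reader; available directly for tables assembled by hand.
#'
#' @param df A data frame with the variant-call columns.
#' @return `df`, invisibly classed as `variant_calls`.
#' @export
validate_variant_calls <- function(df) {
  required <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                "vaf", "pop_freq_max", "effect", "hotspot")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant-call table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    bad <- which(!is.finite(df$vaf) | df$vaf < 0 | df$vaf > 1)
    if (length(bad) > 0L) {
      stop("vaf outside [0, 1] in row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    bad <- which(is.na(df$pos) | df$pos < 1L)
    if (length(bad) > 0L) {
      stop("pos must be a 1-based position >= 1 in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad <- which(df$ref == df$alt)
    if (length(bad) > 0L) {
      stop("ref and alt alleles are identical in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad <- which(!df$effect %in% effect_levels())
    if (length(bad) > 0L) {
      stop("unrecognised effect class in row(s): ",
           paste(bad, collapse = ", "), "; expected one of ",
           paste(effect_levels(), collapse = ", "), call. = FALSE)
    }
    bad <- which(!is.na(df$pop_freq_max) &
                   (df$pop_freq_max < 0 | df$pop_freq_max > 1))
    if (length(bad) > 0L) {
      stop("pop_freq_max outside [0, 1] in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if ("timepoint" %in% names(df)) {
      bad <- which(!df$timepoint %in% timepoint_levels())
      if (length(bad) > 0L) {
        stop("timepoint must be 'pre_nac' or 'post_nac' in row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  class(df) <- unique(c("variant_calls", class(df)))
  invisible(df)
}

## Accepts "0.35" (fraction) or "0.5%" (percentage); only an explicit "%"
## suffix triggers the /100 conversion.
parse_vaf <- function(x, line = NULL) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  val <- suppressWarnings(as.numeric(sub("%$", "", x)))
  val[pct] <- val[pct] / 100
  bad <- which(is.na(val) | val < 0 | val > 1)
  if (length(bad) > 0L) {
    where <- if (is.null(line)) bad else line[bad]
    stop("malformed or out-of-range VAF ", dQuote(x[bad[1]]),
         " at line ", where[1], call. = FALSE)
  }
  val
}

#' Read annotated somatic variant calls from disk
#'
#' Two dialects are supported. `"tsv"` (the canonical format) is a
#' tab-separated table whose header carries the `variant_calls` column names
#' (`timepoint` optional). `"vcf"` is a VCF v4.2 convenience dialect whose
#' per-record INFO field carries `AF` (the VAF), `POPFREQMAX`, `EFFECT`,
#' `HOTSPOT` and optionally `GENE`; the sample identifier is taken from
#' `sample_id` (default: the file name without extension).
#'
#' VAF values may be given as fractions (`"0.35"`) or percentage strings
#' (`"0.5%"`, converted to 0.005); a bare number is always a fraction.
#' An empty or `NA` `pop_freq_max` is preserved as missing. Malformed rows
#' and out-of-range VAFs raise an error naming the offending line.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_id Sample identifier used for the VCF dialect (VCF records
#'   carry no per-row sample column).
#' @return A `variant_calls` data frame, one row per record.
#' @seealso [variant_calls()], [filter_variants()]
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") read_variant_tsv(path) else {
    read_variant_vcf(path, sample_id = sample_id)
  }
}

read_variant_tsv <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  required <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                "vaf", "pop_freq_max", "effect", "hotspot")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("TSV header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # header is line 1
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) & !is.na(raw$pos))
  if (length(bad) > 0L) {
    stop("malformed pos ", dQuote(raw$pos[bad[1]]), " at line ",
         lines[bad[1]], call. = FALSE)
  }
  hot <- parse_logical(raw$hotspot)
  bad <- which(is.na(hot))
  if (length(bad) > 0L) {
    stop("malformed hotspot flag ", dQuote(raw$hotspot[bad[1]]),
         " at line ", lines[bad[1]], call. = FALSE)
  }
  pfm <- suppressWarnings(as.numeric(raw$pop_freq_max))
  bad <- which(is.na(pfm) & !is.na(raw$pop_freq_max))
  if (length(bad) > 0L) {
    stop("malformed pop_freq_max ", dQuote(raw$pop_freq_max[bad[1]]),
         " at line ", lines[bad[1]], call. = FALSE)
  }
  variant_calls(
    sample_id = raw$sample_id, gene = raw$gene, chrom = raw$chrom,
    pos = pos, ref = raw$ref, alt = raw$alt,
    vaf = parse_vaf(raw$vaf, line = lines),
    pop_freq_max = pfm, effect = raw$effect, hotspot = hot,
    timepoint = if ("timepoint" %in% names(raw)) raw$timepoint else NULL
  )
}

parse_logical <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

## VCF v4.2 convenience dialect: parsing is delegated to vcfR; this function
## only maps the fixed columns and the INFO keys AF, POPFREQMAX, EFFECT,
## HOTSPOT, GENE onto the variant_calls schema.
read_variant_vcf <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf$", "", basename(path), ignore.case = TRUE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0L) return(variant_calls())
  info <- vcf@fix[, "INFO"]
  af <- vcfR::extract.info(vcf, element = "AF")
  if (anyNA(af)) {
    stop("VCF record without AF INFO key (record ",
         which(is.na(af))[1], ")", call. = FALSE)
  }
  hot_kv <- parse_logical(vcfR::extract.info(vcf, element = "HOTSPOT"))
  hot_flag <- grepl("(^|;)HOTSPOT(;|$)", info)  # bare Flag form
  effect <- vcfR::extract.info(vcf, element = "EFFECT")
  effect[is.na(effect)] <- "other"
  gene <- vcfR::extract.info(vcf, element = "GENE")
  variant_calls(
    sample_id = sample_id,
    gene = ifelse(is.na(gene), "", gene),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    vaf = parse_vaf(af),
    pop_freq_max = suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = "POPFREQMAX"))),
    effect = effect,
    hotspot = ifelse(is.na(hot_kv), hot_flag, hot_kv)
  )
}

#' Write a variant-call table to the canonical TSV format
#'
#' @param calls A `variant_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  validate_variant_calls(calls)
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
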