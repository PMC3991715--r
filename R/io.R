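norm_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  suppressWarnings(num <- as.numeric(x))
  ifelse(is.na(num), NA_real_, num)
}

#' Read a genotype table
#'
#' Two formats are supported.  `"tsv"`: header `chrom`, `pos` (1-based),
#' `variant_id`, then one column per sample with values `AA/AB/BB/NC`
#' (`BA` is normalised to `AB`).  `"vcf"`: a biallelic, diploid VCF whose
#' GT fields map 0/0 to `AA`, 0/1 or 1/0 to `AB`, 1/1 to `BB` and missing
#' to `NC`; multi-allelic and non-diploid records are skipped and counted.
#' Only autosomes (chromosomes 1-22, with or without a `chr` prefix) are
#' kept in either mode.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Tibble sorted by (`chrom`, `pos`) with attribute `skipped`
#'   giving the number of non-autosomal / non-biallelic records dropped.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE)
    stopifnot(all(c("chrom", "pos", "variant_id") %in% names(tab)))
    tab$chrom <- norm_chrom(tab$chrom)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(vcfR::getFIX(vcf))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    biallelic <- !grepl(",", fix$ALT) & nchar(fix$ALT) > 0
    tab <- tibble::tibble(chrom = norm_chrom(fix$CHROM),
                          pos = as.numeric(fix$POS),
                          variant_id = fix$ID)
    conv <- function(g) {
      g <- sub("\\|", "/", g)
      dplyr::case_when(
        g %in% "0/0" ~ "AA",
        g %in% c("0/1", "1/0") ~ "AB",
        g %in% "1/1" ~ "BB",
        TRUE ~ "NC")
    }
    for (s in colnames(gt)) tab[[s]] <- conv(gt[, s])
    tab <- tab[biallelic, , drop = FALSE]
  }
  auto <- !is.na(tab$chrom) & tab$chrom >= 1 & tab$chrom <= 22
  skipped <- sum(!auto)
  tab <- tab[auto, , drop = FALSE]
  call_cols <- setdiff(names(tab), c("chrom", "pos", "variant_id"))
  for (s in call_cols) {
    v <- toupper(tab[[s]])
    v[v == "BA"] <- "AB"
    bad <- !v %in% genotype_codes()
    if (any(bad)) {
      stop("invalid genotype call '", v[which(bad)[1]], "' at row ",
           which(bad)[1], " of column ", s, call. = FALSE)
    }
    tab[[s]] <- v
  }
  if (anyDuplicated(tab[c("chrom", "pos", "variant_id")])) {
    stop("duplicate (chrom, pos, variant_id) records", call. = FALSE)
  }
  out <- dplyr::arrange(tab, .data$chrom, .data$pos)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype table
#'
#' @param genotypes Tibble as returned by [read_genotypes()].
#' @param path Output path (TSV).
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, progress = FALSE)
  invisible(path)
}

#' Read a chromosome-arm table
#'
#' TSV with columns `chrom`, `arm`, `start`, `end`, `centromere_boundary`
#' (1-based inclusive).
#'
#' @param path File path.
#' @return Arm tibble.
#' @export
read_arm_table <- function(path) {
  arms <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  arms$chrom <- norm_chrom(arms$chrom)
  check_arm_table(arms)
  arms
}

#' Read gene regions from BED4 plus membership lists
#'
#' BED4 columns: chrom, start (0-based), end, gene name; converted to
#' 1-based inclusive internally.  Duplicate names are resolved to the
#' longest entry.  The optional membership files hold one gene symbol per
#' line and set the `fragile_site` / `cancer_census` flags.
#'
#' @param path BED4 file.
#' @param fragile_path,census_path Optional membership list files.
#' @return Gene tibble with columns `gene`, `chrom`, `start`, `end`,
#'   `fragile_site`, `cancer_census`.
#' @export
read_gene_bed <- function(path, fragile_path = NULL, census_path = NULL) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "gene"),
                         show_col_types = FALSE, progress = FALSE)
  genes <- tibble::tibble(gene = bed$gene,
                          chrom = norm_chrom(bed$chrom),
                          start = bed$start + 1,
                          end = bed$end) |>
    dedupe_genes()
  fragile <- if (is.null(fragile_path)) character() else {
    readr::read_lines(fragile_path, progress = FALSE)
  }
  census <- if (is.null(census_path)) character() else {
    readr::read_lines(census_path, progress = FALSE)
  }
  genes$fragile_site <- genes$gene %in% fragile
  genes$cancer_census <- genes$gene %in% census
  genes
}

#' Read CNV segments from a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, state (`loss/neutral/gain`),
#' sample; converted to 1-based inclusive coordinates.
#'
#' @param path File path.
#' @return CNV tibble with columns `chrom`, `start`, `end`, `state`,
#'   `sample`.
#' @export
read_cnv_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "state", "sample"),
                         show_col_types = FALSE, progress = FALSE)
  stopifnot(all(bed$state %in% c("loss", "neutral", "gain")))
  tibble::tibble(chrom = norm_chrom(bed$chrom), start = bed$start + 1,
                 end = bed$end, state = bed$state, sample = bed$sample)
}

#' Variant-level ingest QC
#'
#' Removes variants whose cohort-wide call rate falls below
#' `min_call_rate` (default 0.95) and variants with more than
#' `max_nocalls` no-calls across the table's samples (default 2, i.e.
#' variants with 3 or more no-calls are removed).
#'
#' @param genotypes Genotype tibble.
#' @param min_call_rate Minimum fraction of non-`NC` calls per variant;
#'   `NULL` disables the filter.
#' @param max_nocalls Maximum allowed `NC` count per variant; `NULL`
#'   disables the filter.
#' @return Filtered tibble with attribute `ingest_report`, a tibble of
#'   removal counts by reason.
#' @export
ingest_qc <- function(genotypes, min_call_rate = 0.95, max_nocalls = 2) {
  call_cols <- setdiff(names(genotypes), c("chrom", "pos", "variant_id"))
  nc <- rowSums(as.matrix(genotypes[call_cols]) == "NC")
  n <- length(call_cols)
  drop_rate <- if (is.null(min_call_rate)) rep(FALSE, nrow(genotypes)) else {
    (n - nc) / n < min_call_rate
  }
  drop_nc <- if (is.null(max_nocalls)) rep(FALSE, nrow(genotypes)) else {
    nc > max_nocalls
  }
  report <- tibble::tibble(
    reason = c("call_rate_below_min", "nocalls_above_max"),
    n_removed = c(sum(drop_rate), sum(drop_nc & !drop_rate)))
  out <- genotypes[!(drop_rate | drop_nc), , drop = FALSE]
  attr(out, "ingest_report") <- report
  out
}

#' Write called tracts as TSV and optionally BED6
#'
#' The TSV keeps 1-based inclusive coordinates; the BED export converts to
#' 0-based half-open.  Files are written even when the tract set is empty
#' (headers only).
#'
#' @param tracts Tract tibble from [call_loh()].
#' @param path Output TSV path.
#' @param bed_path Optional BED6 path.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(tracts, path, bed_path = NULL) {
  readr::write_tsv(tracts, path, progress = FALSE)
  if (!is.null(bed_path)) {
    bed <- tibble::tibble(chrom = tracts$chrom,
                          start = tracts$start - 1,
                          end = tracts$end,
                          name = paste0(tracts$sample, "_",
                                        seq_len(nrow(tracts))),
                          score = tracts$n_events,
                          strand = ".")
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read tracts exported as BED6 back to 1-based coordinates
#'
#' @param path BED6 file written by [write_tracts()].
#' @return Tibble with columns `chrom`, `start`, `end`, `name`,
#'   `n_events`.
#' @export
read_tracts_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  tibble::tibble(chrom = norm_chrom(bed$chrom), start = bed$start + 1,
                 end = bed$end, name = bed$name, n_events = bed$score)
}

#' Write a provenance sidecar
#'
#' Records the effective parameters, seed and package version alongside
#' any analysis output so runs are reproducible from their artifacts.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters (e.g. an [loh_params()] or
#'   [perm_config()] object).
#' @param seed Seed used.
#' @param inputs Optional named character vector of input descriptions.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, params = list(), seed = NA_integer_,
                             inputs = character()) {
  jsonlite::write_json(list(
    tool = "lohtrack",
    version = as.character(utils::packageVersion("lohtrack")),
    seed = seed,
    params = unclass(params),
    inputs = as.list(inputs)
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
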