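#' Genotype call codes
#'
#' Genotype calls at biallelic loci are encoded as two-letter strings over the
#' allele codes A and B: `"AA"`, `"AB"`, `"BB"`, plus the distinguished no-call
#' value `"NC"`.  Allele order carries no meaning (`"BA"` is normalised to
#' `"AB"` at ingest).
#'
#' @return Character vector of the four valid call codes.
#' @export
#' @examples
#' genotype_codes()
genotype_codes <- function() c("AA", "AB", "BB", "NC")

#' The ten germline-to-tissue transition categories
#'
#' Every pair of a germline call and a tissue call at one locus falls into
#' exactly one of ten categories.  The informative one for LOH is
#' `HET_TO_HOM`: a locus heterozygous in germline that has become homozygous
#' in tissue.  `MONOALLELIC_MUTATION` is germline homozygote to tissue
#' heterozygote sharing one allele (AA->AB); `BIALLELIC_MUTATION` is germline
#' homozygote to the opposite homozygote (AA->BB).
#'
#' @return Character vector of the ten category names, in a fixed order.
#' @export
transition_types <- function() {
  c("HET_TO_HOM", "HOM_TO_HOM", "HET_TO_HET", "HET_TO_UNK", "UNK_TO_UNK",
    "UNK_TO_HET", "UNK_TO_HOM", "HOM_TO_UNK",
    "MONOALLELIC_MUTATION", "BIALLELIC_MUTATION")
}

#' Zygosity of a genotype call
#'
#' @param call Character vector of genotype calls (see [genotype_codes()]).
#' @return Character vector with values `"HET"`, `"HOM"` or `"UNK"`.
#' @export
#' @examples
#' zygosity(c("AA", "AB", "NC"))
zygosity <- function(call) {
  stopifnot(all(call %in% genotype_codes()))
  dplyr::case_when(
    call == "AB" ~ "HET",
    call == "NC" ~ "UNK",
    TRUE ~ "HOM"
  )
}

#' Classify germline-to-tissue genotype transitions
#'
#' Vectorised total classification of call pairs into the ten transition
#' categories (see [transition_types()]).  The classification is symmetric
#' under relabelling the two alleles (A<->B in both samples).
#'
#' @param germline,tissue Character vectors of genotype calls of equal
#'   length, values among [genotype_codes()].
#' @return Factor of transition categories with levels [transition_types()].
#' @export
#' @examples
#' classify_transitions(c("AB", "AA", "AA"), c("AA", "BB", "AB"))
classify_transitions <- function(germline, tissue) {
  stopifnot(length(germline) == length(tissue))
  stopifnot(all(germline %in% genotype_codes()),
            all(tissue %in% genotype_codes()))
  zg <- zygosity(germline)
  zt <- zygosity(tissue)
  out <- dplyr::case_when(
    zg == "HET" & zt == "HOM" ~ "HET_TO_HOM",
    zg == "HET" & zt == "HET" ~ "HET_TO_HET",
    zg == "HET" & zt == "UNK" ~ "HET_TO_UNK",
    zg == "UNK" & zt == "UNK" ~ "UNK_TO_UNK",
    zg == "UNK" & zt == "HET" ~ "UNK_TO_HET",
    zg == "UNK" & zt == "HOM" ~ "UNK_TO_HOM",
    zg == "HOM" & zt == "UNK" ~ "HOM_TO_UNK",
    zg == "HOM" & zt == "HET" ~ "MONOALLELIC_MUTATION",
    zg == "HOM" & zt == "HOM" & germline == tissue ~ "HOM_TO_HOM",
    zg == "HOM" & zt == "HOM" & germline != tissue ~ "BIALLELIC_MUTATION"
  )
  factor(out, levels = transition_types())
}

#' Assign loci to chromosome arms
#'
#' Each locus is assigned the unique arm whose closed interval
#' `[start, end]` contains its position.  Loci falling in a gap between arms
#' (e.g. inside the centromere) raise an error unless `strict = FALSE`, in
#' which case they get `NA`.
#'
#' @param loci Data frame with columns `chrom` and `pos` (1-based).
#' @param arms Arm table: data frame with columns `chrom`, `arm` (`"p"` or
#'   `"q"`), `start`, `end`, `centromere_boundary` (all 1-based inclusive).
#' @param strict Error on unassignable loci?  Default `TRUE`.
#' @return Character vector of arm labels (`"<chrom><arm>"`, e.g. `"1p"`),
#'   parallel to the rows of `loci`.
#' @export
assign_arm <- function(loci, arms, strict = TRUE) {
  stopifnot(all(c("chrom", "pos") %in% names(loci)))
  check_arm_table(arms)
  lab <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(arms))) {
    hit <- loci$chrom == arms$chrom[i] &
      loci$pos >= arms$start[i] & loci$pos <= arms$end[i]
    lab[hit] <- paste0(arms$chrom[i], arms$arm[i])
  }
  if (strict && anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    stop("locus ", loci$chrom[bad], ":", loci$pos[bad],
         " falls outside every annotated arm", call. = FALSE)
  }
  lab
}

check_arm_table <- function(arms) {
  need <- c("chrom", "arm", "start", "end")
  stopifnot(all(need %in% names(arms)))
  stopifnot(all(arms$start <= arms$end))
  invisible(arms)
}

#' Validate a genome annotation
#'
#' Report-only consistency checks on an arm table and a gene table:
#' overlapping arms on one chromosome, genes not fully covered by any arm,
#' and duplicate gene names (which ingest should have resolved to the
#' longest entry).
#'
#' @param arms Arm table (see [assign_arm()]).
#' @param genes Gene table: data frame with columns `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @return Tibble of findings with columns `check`, `detail`; zero rows for
#'   a well-formed annotation.
#' @export
validate_annotation <- function(arms, genes = NULL) {
  check_arm_table(arms)
  findings <- list()
  for (ch in unique(arms$chrom)) {
    sub <- dplyr::arrange(arms[arms$chrom == ch, , drop = FALSE], .data$start)
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      findings[[length(findings) + 1]] <- tibble::tibble(
        check = "overlapping_arms",
        detail = paste0("chromosome ", ch, " has overlapping arm intervals"))
    }
  }
  if (!is.null(genes) && nrow(genes) > 0) {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
    covered <- vapply(seq_len(nrow(genes)), function(i) {
      any(arms$chrom == genes$chrom[i] &
            arms$start <= genes$start[i] & arms$end >= genes$end[i])
    }, logical(1))
    if (any(!covered)) {
      findings[[length(findings) + 1]] <- tibble::tibble(
        check = "gene_outside_arms",
        detail = paste0("gene ", genes$gene[!covered],
                        " not fully covered by any arm"))
    }
    dup <- unique(genes$gene[duplicated(genes$gene)])
    if (length(dup) > 0) {
      findings[[length(findings) + 1]] <- tibble::tibble(
        check = "duplicate_gene",
        detail = paste0("gene ", dup,
                        " has multiple entries; keep the longest"))
    }
  }
  if (length(findings) == 0) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

#' Resolve duplicate gene entries to the longest
#'
#' Where a gene symbol has several entries, only the longest interval is
#' retained (ties broken by first occurrence).
#'
#' @param genes Gene table with columns `gene`, `chrom`, `start`, `end`.
#' @return Gene tibble with unique `gene` values.
#' @export
dedupe_genes <- function(genes) {
  genes |>
    dplyr::mutate(.len = .data$end - .data$start + 1) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$.len)) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::select(-".len") |>
    dplyr::arrange(.data$chrom, .data$start)
}
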