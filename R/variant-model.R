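#' Parse missense-variant labels
#'
#' Parses labels of the form `"L1341P"` (reference amino acid, 1-based
#' protein position, alternate amino acid) into a variant record table.
#' Positions are protein coordinates on dysferlin isoform 8 (NM_003494),
#' the construct the assay expresses. Zygosity and evidence annotations
#' default to `"unknown"` / `"none"` and are filled from a variant table
#' (see [read_variant_table()]) when available.
#'
#' @param label Character vector of labels matching
#'   `<ref_aa><position><alt_aa>` with one-letter amino-acid codes.
#' @return A tibble with columns `label`, `ref_aa`, `position`, `alt_aa`,
#'   `zygosity` (`"homozygous"`, `"compound_het"` or `"unknown"`) and
#'   `evidence` (list-column of character vectors, default `"none"`).
#' @examples
#' parse_pmm(c("L1341P", "A170E"))
#' @export
parse_pmm <- function(label) {
  stopifnot(is.character(label))
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  pat <- sprintf("^([%s])([0-9]+)([%s])$", aa, aa)
  bad <- label[!grepl(pat, label)]
  if (length(bad) > 0) {
    abort(sprintf("malformed variant label(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  ref <- sub(pat, "\\1", label)
  pos <- as.integer(sub(pat, "\\2", label))
  alt <- sub(pat, "\\3", label)
  if (any(pos < 1)) {
    abort(sprintf("variant position must be >= 1: %s",
                  paste(label[pos < 1], collapse = ", ")))
  }
  same <- ref == alt
  if (any(same)) {
    abort(sprintf("reference and alternate amino acids are identical: %s",
                  paste(label[same], collapse = ", ")))
  }
  tibble::tibble(
    label = label,
    ref_aa = ref,
    position = pos,
    alt_aa = alt,
    zygosity = "unknown",
    evidence = rep(list("none"), length(label))
  )
}

#' Format variant records back to labels
#'
#' Inverse of [parse_pmm()]: `format_pmm(parse_pmm(x))` is identical to `x`
#' for any valid label vector.
#'
#' @param records Tibble with columns `ref_aa`, `position`, `alt_aa`.
#' @return Character vector of labels.
#' @export
format_pmm <- function(records) {
  paste0(records$ref_aa, records$position, records$alt_aa)
}

#' Read a variant table
#'
#' Reads a TSV with columns `label`, optional `zygosity`, optional
#' `evidence` (semicolon-separated categories) and optional
#' `icc_pm_localized` (0/1 immunocytochemistry call), parsing the labels
#' with [parse_pmm()].
#'
#' @param path Path to the TSV file.
#' @return A variant record tibble; extra columns are carried through.
#' @export
read_variant_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"label" %in% names(raw)) {
    abort("variant table must have a `label` column")
  }
  rec <- parse_pmm(raw$label)
  if ("zygosity" %in% names(raw)) {
    ok <- raw$zygosity %in% c("homozygous", "compound_het", "unknown")
    if (!all(ok)) {
      abort(sprintf("unknown zygosity value(s): %s",
                    paste(unique(raw$zygosity[!ok]), collapse = ", ")))
    }
    rec$zygosity <- raw$zygosity
  }
  if ("evidence" %in% names(raw)) {
    rec$evidence <- lapply(raw$evidence, function(e) {
      if (is.na(e) || e == "") "none" else strsplit(e, ";", fixed = TRUE)[[1]]
    })
    cats <- c("other_dystrophy", "normal_protein_level", "splicing_defect",
              "cis_with_pathogenic", "two_other_pathogenic", "clinvar_benign",
              "none")
    seen <- unique(unlist(rec$evidence))
    if (!all(seen %in% cats)) {
      abort(sprintf("unknown evidence categor%s: %s",
                    if (sum(!seen %in% cats) > 1) "ies" else "y",
                    paste(setdiff(seen, cats), collapse = ", ")))
    }
  }
  extra <- setdiff(names(raw), c("label", "zygosity", "evidence"))
  dplyr::bind_cols(rec, raw[extra])
}

#' Read a protein domain annotation
#'
#' Reads domain boundaries from TSV (columns `name`, `start`, `end`,
#' `family`) or JSON (array of objects with those fields). Coordinates are
#' 1-based inclusive protein positions; entries must be non-overlapping.
#' No authoritative boundary set is bundled: the included file
#' `dysf_domains_synthetic.tsv` is an illustrative synthetic annotation
#' for tests and examples only.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return A validated domain annotation tibble.
#' @examples
#' ann <- read_domain_annotation(
#'   system.file("extdata", "dysf_domains_synthetic.tsv",
#'               package = "dysfscreen"))
#' head(ann)
#' @export
read_domain_annotation <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ann <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    ann <- readr::read_tsv(path, show_col_types = FALSE)
  }
  validate_domain_annotation(ann)
}

#' Validate a domain annotation table
#'
#' @param annotation Tibble with columns `name`, `start`, `end`, `family`
#'   (one of `"C2"`, `"FerA"`, `"DysF"`, `"TM"`, `"other"`).
#' @return The annotation, sorted by `start`, invisibly validated.
#' @export
validate_domain_annotation <- function(annotation) {
  need <- c("name", "start", "end", "family")
  missing <- setdiff(need, names(annotation))
  if (length(missing) > 0) {
    abort(sprintf("domain annotation lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  fams <- c("C2", "FerA", "DysF", "TM", "other")
  if (!all(annotation$family %in% fams)) {
    abort(sprintf("unknown domain famil(y/ies): %s",
                  paste(setdiff(annotation$family, fams), collapse = ", ")))
  }
  if (any(annotation$start < 1) || any(annotation$start > annotation$end)) {
    abort("domain entries need 1 <= start <= end")
  }
  ann <- dplyr::arrange(tibble::as_tibble(annotation), .data$start)
  if (nrow(ann) > 1 && any(ann$start[-1] <= ann$end[-nrow(ann)])) {
    abort("domain entries overlap after sorting")
  }
  ann
}

#' Assign variants to protein domains
#'
#' Sets each record's `domain` to the name of the annotation entry whose
#' interval contains its position (1-based inclusive ends), or
#' `"inter-domain"` when no entry contains it; the entry's `family` is
#' recorded alongside for enrichment tallies.
#'
#' @param records Variant record tibble (see [parse_pmm()]).
#' @param annotation Domain annotation tibble
#'   (see [read_domain_annotation()]).
#' @return `records` with `domain` and `family` columns added/replaced.
#' @export
assign_domain <- function(records, annotation) {
  ann <- validate_domain_annotation(annotation)
  idx <- vapply(records$position, function(p) {
    i <- which(ann$start <= p & p <= ann$end)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  records$domain <- ifelse(is.na(idx), "inter-domain", ann$name[idx])
  records$family <- ifelse(is.na(idx), "inter-domain", ann$family[idx])
  records
}

#' Tally a variant registry by classification stratum
#'
#' Summarizes classified variant records the way a registry report does:
#' homozygous variants below vs at-or-above the defective threshold (with
#' integer percentages, ties rounded away from zero), plus counts per
#' non-pathogenicity evidence category and their total.
#'
#' @param records Variant record tibble carrying a logical `defective`
#'   column (from [classify()]) and optionally `zygosity` and `evidence`.
#' @return A tibble with columns `stratum`, `count`, `total`, `percent`
#'   (`percent` is `NA` for evidence rows). Empty input gives an empty
#'   summary, not an error.
#' @examples
#' rec <- parse_pmm(c("L1341P", "A170E", "R555W"))
#' rec$zygosity <- c("homozygous", "homozygous", "compound_het")
#' rec$defective <- c(TRUE, FALSE, TRUE)
#' registry_tally(rec)
#' @export
registry_tally <- function(records) {
  empty <- tibble::tibble(stratum = character(), count = integer(),
                          total = integer(), percent = numeric())
  if (nrow(records) == 0) {
    return(empty)
  }
  if (!"defective" %in% names(records)) {
    abort("records need a logical `defective` column (see classify())")
  }
  out <- list()
  if ("zygosity" %in% names(records)) {
    homo <- records[records$zygosity == "homozygous", ]
    n_homo <- nrow(homo)
    n_below <- sum(homo$defective)
    out$homo <- tibble::tibble(
      stratum = c("homozygous_below_threshold", "homozygous_above_threshold"),
      count = c(n_below, n_homo - n_below),
      total = n_homo,
      percent = if (n_homo > 0) {
        round_half_away(100 * c(n_below, n_homo - n_below) / n_homo)
      } else {
        NA_real_
      }
    )
  }
  out$all <- tibble::tibble(
    stratum = c("below_threshold", "above_threshold"),
    count = c(sum(records$defective), sum(!records$defective)),
    total = nrow(records),
    percent = round_half_away(
      100 * c(sum(records$defective), sum(!records$defective)) /
        nrow(records))
  )
  if ("evidence" %in% names(records)) {
    ev <- unlist(records$evidence)
    ev <- ev[ev != "none"]
    if (length(ev) > 0) {
      tab <- table(ev)
      out$evidence <- tibble::tibble(
        stratum = paste0("evidence_", names(tab)),
        count = as.integer(tab),
        total = NA_integer_,
        percent = NA_real_
      )
      out$evidence_total <- tibble::tibble(
        stratum = "evidence_total",
        count = length(ev),
        total = NA_integer_,
        percent = NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}
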