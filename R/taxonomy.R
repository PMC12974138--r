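# Rank collapsing of feature tables via lineage strings of the
# "k__...;p__...;c__...;o__...;f__...;g__..." form.

RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
           family = "f", genus = "g", species = "s")

# split a lineage string into a named character vector over RANKS;
# unresolved ranks (absent, empty, or bare prefix) come back as NA
parse_lineage <- function(lineage) {
  parts <- stringr::str_split(lineage, ";")[[1]]
  parts <- stringr::str_trim(parts)
  out <- setNames(rep(NA_character_, length(RANKS)), names(RANKS))
  for (p in parts) {
    m <- stringr::str_match(p, "^([kpcofgs])__(.*)$")
    if (!is.na(m[1, 1])) {
      rank <- names(RANKS)[match(m[1, 2], RANKS)]
      val <- m[1, 3]
      if (nzchar(val) && !grepl("^(unclassified|unidentified|uncultured)?$", val,
                                ignore.case = TRUE)) {
        out[rank] <- val
      }
    }
  }
  out
}

#' Collapse a feature table to a taxonomic rank
#'
#' Counts are summed over features sharing the lineage up to `rank`.
#' Features unresolved at `rank` are pooled per nearest resolved ancestor
#' under an `un_<prefix>__<ancestor>` bucket (e.g. `un_f__Lachnospiraceae`
#' for a genus-unresolved member of a known family), mirroring common
#' amplicon display conventions. Per-sample totals are conserved.
#'
#' @param table wide count tibble (`sample_id` + feature columns).
#' @param taxonomy tibble with `taxon_id` and `lineage` columns.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return wide count tibble with one column per collapsed taxon.
#' @export
collapse_rank <- function(table, taxonomy, rank = "genus") {
  if (!rank %in% names(RANKS)) {
    abort(paste0("unknown rank: ", rank), class = "gutstab_unknown_rank")
  }
  m <- as_count_matrix(table)
  missing <- setdiff(colnames(m), taxonomy$taxon_id)
  if (length(missing)) {
    abort(paste("taxa absent from taxonomy:", paste(head(missing, 5), collapse = ", ")),
          class = "gutstab_missing_taxon")
  }
  lineages <- lapply(taxonomy$lineage[match(colnames(m), taxonomy$taxon_id)],
                     parse_lineage)
  ridx <- match(rank, names(RANKS))
  labels <- vapply(lineages, function(lin) {
    if (!is.na(lin[[ridx]])) return(lin[[ridx]])
    # nearest resolved ancestor above the target rank
    for (j in rev(seq_len(ridx - 1))) {
      if (!is.na(lin[[j]])) {
        return(paste0("un_", RANKS[[j]], "__", lin[[j]]))
      }
    }
    "un_unclassified"
  }, character(1))
  grouped <- rowsum(t(m), group = labels)   # taxa x samples summed by label
  as_count_tibble(t(grouped))
}
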