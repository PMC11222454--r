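# miRNA shortlisting cascade and miRNA->mRNA target interaction (MTI)
# extraction and annotation.

#' Extract inferred miRNA-mRNA target interactions
#'
#' One record per distinct (miRNA, mRNA) pair connected by a retained,
#' direct miRNA->mRNA arc in at least one per-time-point network, with the
#' set of time-points at which the arc is retained. mRNA->miRNA arcs and
#' indirect (multi-hop) effects are not counted as targets.
#'
#' @param networks named list of filtered `StrengthNetwork`s, one per
#'   time-point (names are the time-point labels).
#' @return data.frame: `mirna`, `mrna`, `timepoints` (list column),
#'   `n_timepoints`.
#' @export
extract_mti <- function(networks) {
  rows <- list()
  for (tp in names(networks)) {
    net <- networks[[tp]]
    arcs <- retained_arcs(net)
    types <- setNames(net$nodes$type, net$nodes$id)
    keep <- types[arcs$from] == "miRNA" & types[arcs$to] == "mRNA"
    if (any(keep))
      rows[[tp]] <- data.frame(mirna = arcs$from[keep], mrna = arcs$to[keep],
                               timepoint = tp, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(mirna = character(0), mrna = character(0),
                      n_timepoints = integer(0)))
  flat <- do.call(rbind, rows)
  key <- paste(flat$mirna, flat$mrna, sep = "\r")
  agg <- split(flat$timepoint, key)
  first <- flat[!duplicated(key), , drop = FALSE]
  ord <- match(unique(key), names(agg))
  out <- data.frame(mirna = first$mirna, mrna = first$mrna,
                    stringsAsFactors = FALSE)
  out$timepoints <- unname(agg[ord])
  out$n_timepoints <- lengths(out$timepoints)
  rownames(out) <- NULL
  out
}

#' Default rat-to-human gene-symbol synonym map
#'
#' The three rat symbols renamed to their human synonyms/orthologues before
#' cross-resource comparison.
#'
#' @return named character vector, rat symbol -> replacement.
#' @export
default_synonym_map <- function() {
  c(Cecr6 = "TMEM121B", Pnmal2 = "PNMA8B", Oasl2 = "OASL")
}

#' Clean and map gene symbols
#'
#' Drops records whose gene symbol is not an official symbol (contains a
#' ".", or starts with "LOC" or "RGD") and applies a synonym map (defaults
#' to [default_synonym_map()]). Idempotent; the removed symbols are kept in
#' the `removed` attribute.
#'
#' @param records an MTI data.frame with an `mrna` column, or a character
#'   vector of symbols.
#' @param synonym_map named character vector old -> new.
#' @return cleaned records (or vector), with attribute `removed`.
#' @export
clean_symbols <- function(records, synonym_map = default_synonym_map()) {
  if (!is.null(synonym_map) && is.null(names(synonym_map)))
    stop_invalid_input("synonym_map must be named")
  vecmode <- is.character(records)
  sym <- if (vecmode) records else records$mrna
  bad <- grepl(".", sym, fixed = TRUE) | startsWith(sym, "LOC") | startsWith(sym, "RGD")
  removed <- unique(sym[bad])
  sym <- sym[!bad]
  hit <- sym %in% names(synonym_map)
  sym[hit] <- unname(synonym_map[sym[hit]])
  if (vecmode) {
    out <- sym
  } else {
    out <- records[!bad, , drop = FALSE]
    out$mrna <- sym
    rownames(out) <- NULL
  }
  attr(out, "removed") <- removed
  out
}

#' Seed-region (nt 2-8) conservation
#'
#' TRUE iff the seed region - nucleotides 2 through 8 inclusive, 1-based (7
#' nucleotides) - is identical between the two mature sequences after
#' uppercasing and U/T unification.
#'
#' @param rat_seq,human_seq mature miRNA sequences (RNA or DNA alphabet),
#'   length >= 8.
#' @return logical flag.
#' @export
seed_conserved <- function(rat_seq, human_seq) {
  norm <- function(s) {
    s <- chartr("tu", "TU", toupper(as.character(s)))
    gsub("T", "U", s, fixed = TRUE)
  }
  a <- norm(rat_seq); b <- norm(human_seq)
  if (nchar(a) < 8 || nchar(b) < 8)
    stop_invalid_input("mature sequence shorter than 8 nt")
  substr(a, 2, 8) == substr(b, 2, 8)
}

#' Assemble per-miRNA records for the shortlisting cascade
#'
#' Combines inferred target counts per time-point (direct retained
#' miRNA->mRNA arcs), human orthology and seed conservation into one row per
#' miRNA in the DE universe.
#'
#' @param mirnas character vector: the dysregulated miRNA universe.
#' @param mti output of [extract_mti()].
#' @param timepoints ordered time-point labels.
#' @param orthology data.frame with columns `rat_id`, `human_id` (rows
#'   absent or `NA` mean no human orthologue).
#' @param rat_seqs,human_seqs named sequence vectors (e.g. from
#'   [read_mature_fasta()]); seed conservation is `NA` unless both are
#'   present for a miRNA.
#' @return data.frame with `rat_id`, `human_id`, `seed_conserved` and one
#'   `targets_<timepoint>` count column per time-point.
#' @export
build_mirna_records <- function(mirnas, mti, timepoints = default_timepoints(),
                                orthology = NULL, rat_seqs = NULL,
                                human_seqs = NULL) {
  counts <- matrix(0L, length(mirnas), length(timepoints),
                   dimnames = list(mirnas, timepoints))
  for (i in seq_len(nrow(mti))) {
    m <- mti$mirna[i]
    if (!m %in% mirnas) next
    counts[m, unlist(mti$timepoints[i])] <- counts[m, unlist(mti$timepoints[i])] + 1L
  }
  human <- rep(NA_character_, length(mirnas))
  if (!is.null(orthology)) {
    ix <- match(mirnas, orthology$rat_id)
    human <- as.character(orthology$human_id[ix])
    human[!is.na(human) & human == ""] <- NA_character_
  }
  cons <- rep(NA, length(mirnas))
  if (!is.null(rat_seqs) && !is.null(human_seqs)) {
    for (i in seq_along(mirnas)) {
      r <- if (mirnas[i] %in% names(rat_seqs)) rat_seqs[[mirnas[i]]] else NULL
      h <- if (!is.na(human[i]) && human[i] %in% names(human_seqs))
        human_seqs[[human[i]]] else NULL
      if (!is.null(r) && !is.null(h)) cons[i] <- seed_conserved(r, h)
    }
  }
  out <- data.frame(rat_id = mirnas, human_id = human, seed_conserved = cons,
                    stringsAsFactors = FALSE)
  cn <- paste0("targets_", timepoints)
  out[cn] <- as.data.frame(counts)
  out
}

target_count_matrix <- function(records) {
  cn <- grep("^targets_", names(records), value = TRUE)
  m <- as.matrix(records[cn])
  rownames(m) <- records$rat_id
  colnames(m) <- sub("^targets_", "", cn)
  m
}

#' The miRNA shortlisting cascade
#'
#' Stage 1 drops miRNAs with no inferred mRNA target at any time-point;
#' stage 2 drops those without a human orthologue; stage 3 keeps those with
#' inferred targets at two or more time-points; stage 4 keeps those whose
#' seed region (nt 2-8) is conserved from rat to human. Stage flags are
#' nested (each stage is a subset of the previous) and per-stage counts are
#' recorded in the `stage_counts` attribute.
#'
#' @param records output of [build_mirna_records()].
#' @return `records` with logical columns `stage1_has_targets`,
#'   `stage2_has_orthologue`, `stage3_multi_timepoint`,
#'   `stage4_seed_conserved`.
#' @export
shortlist_cascade <- function(records) {
  counts <- target_count_matrix(records)
  s1 <- rowSums(counts) > 0
  s2 <- s1 & !is.na(records$human_id)
  s3 <- s2 & rowSums(counts > 0) >= 2
  s4 <- s3 & !is.na(records$seed_conserved) & records$seed_conserved
  records$stage1_has_targets <- unname(s1)
  records$stage2_has_orthologue <- unname(s2)
  records$stage3_multi_timepoint <- unname(s3)
  records$stage4_seed_conserved <- unname(s4)
  attr(records, "stage_counts") <- c(
    input = nrow(records),
    excluded_no_targets = sum(!s1),
    excluded_no_orthologue = sum(s1 & !s2),
    remaining_after_exclusions = sum(s2),
    multi_timepoint = sum(s3),
    seed_conserved = sum(s4))
  records
}

#' Recurrence tables of shortlisted-miRNA targeting
#'
#' Table 1 lists the MTIs of shortlisted miRNAs whose target mRNA is DE at
#' two or more time-points. Table 2 lists, per time-point, the mRNAs
#' targeted by more than two shortlisted miRNAs, with the miRNA count.
#'
#' @param mti output of [extract_mti()].
#' @param shortlist character vector of shortlisted miRNA ids.
#' @param de DE table (columns `entity_id`, `timepoint`, `de`).
#' @return list with `recurrent_target_mtis` and `multi_targeted_mrnas`.
#' @export
recurrence_tables <- function(mti, shortlist, de) {
  de_tp <- with(de[de$de, , drop = FALSE], split(timepoint, entity_id))
  n_de_tp <- lengths(lapply(de_tp, unique))
  keep <- mti$mirna %in% shortlist &
    mti$mrna %in% names(n_de_tp)[n_de_tp >= 2]
  t1 <- mti[keep, , drop = FALSE]
  rownames(t1) <- NULL

  rows <- list()
  short_mti <- mti[mti$mirna %in% shortlist, , drop = FALSE]
  if (nrow(short_mti)) {
    flat <- do.call(rbind, lapply(seq_len(nrow(short_mti)), function(i)
      data.frame(mirna = short_mti$mirna[i], mrna = short_mti$mrna[i],
                 timepoint = unlist(short_mti$timepoints[i]),
                 stringsAsFactors = FALSE)))
    agg <- stats::aggregate(mirna ~ mrna + timepoint, flat,
                            function(m) length(unique(m)))
    names(agg)[3] <- "n_mirnas"
    rows <- agg[agg$n_mirnas > 2, , drop = FALSE]
    rownames(rows) <- NULL
  } else {
    rows <- data.frame(mrna = character(0), timepoint = character(0),
                       n_mirnas = integer(0))
  }
  list(recurrent_target_mtis = t1, multi_targeted_mrnas = rows)
}

#' Z-score normalised target-count heatmap matrix
#'
#' Per miRNA, the target count is z-scored (population standard deviation)
#' across the time-points where the miRNA is present in the network; absent
#' time-points stay `NA`. Rows with a single defined time-point are marked
#' non-normalisable, constant rows map to zeros; both are listed in the
#' `degenerate` attribute.
#'
#' @param counts matrix miRNAs x time-points of target counts, `NA` where
#'   the miRNA has no network presence.
#' @return matrix of the same shape with attributes `non_normalisable` and
#'   `degenerate`.
#' @export
normalized_degree_heat <- function(counts) {
  counts <- as.matrix(counts)
  out <- counts * NA_real_
  nonnorm <- character(0); degen <- character(0)
  for (i in seq_len(nrow(counts))) {
    ok <- !is.na(counts[i, ])
    v <- counts[i, ok]
    if (length(v) < 2) {
      nonnorm <- c(nonnorm, rownames(counts)[i])
      next
    }
    sdv <- sqrt(mean((v - mean(v))^2))
    if (sdv == 0) {
      out[i, ok] <- 0
      degen <- c(degen, rownames(counts)[i])
    } else {
      out[i, ok] <- (v - mean(v)) / sdv
    }
  }
  attr(out, "non_normalisable") <- nonnorm
  attr(out, "degenerate") <- degen
  out
}

#' Annotate MTIs against external interaction resources
#'
#' Joins a predicted-interaction table (miRNA, gene, confidence class),
#' validated and iCLIP interaction lists, and human dysregulation lists
#' onto the inferred MTIs. Matching is on the human miRNA id (via the
#' orthology map when given, else the rat id) and the gene symbol. The MTI
#' set itself is never changed, only flag/class columns are added.
#' Malformed resource rows (missing fields) are skipped with a warning.
#'
#' @param mti output of [extract_mti()] (after [clean_symbols()]).
#' @param prediction data.frame `mirna`, `gene`, `confidence` (classes
#'   Very High / High / Medium / Low).
#' @param validated,iclip data.frames with columns `mirna`, `gene`.
#' @param human_de_mirna,human_de_mrna character vectors of dysregulated
#'   human ids/symbols (already filtered at the source thresholds).
#' @param orthology optional data.frame `rat_id`, `human_id`.
#' @return `mti` with added `human_mirna`, `confidence`, `validated`,
#'   `iclip`, `human_dysregulated_mirna`, `human_dysregulated_mrna`.
#' @export
annotate_resources <- function(mti, prediction = NULL, validated = NULL,
                               iclip = NULL, human_de_mirna = NULL,
                               human_de_mrna = NULL, orthology = NULL) {
  human <- mti$mirna
  if (!is.null(orthology)) {
    ix <- match(mti$mirna, orthology$rat_id)
    human <- as.character(orthology$human_id[ix])
  }
  mti$human_mirna <- human
  key <- paste(human, mti$mrna, sep = "\r")

  clean_pairs <- function(df, what) {
    if (is.null(df)) return(NULL)
    ok <- !is.na(df[[1]]) & !is.na(df[[2]]) & df[[1]] != "" & df[[2]] != ""
    if (!all(ok))
      warning(sprintf("%s: skipped %d malformed row(s)", what, sum(!ok)))
    df[ok, , drop = FALSE]
  }

  mti$confidence <- NA_character_
  if (!is.null(prediction)) {
    prediction <- clean_pairs(prediction, "prediction table")
    pkey <- paste(prediction$mirna, prediction$gene, sep = "\r")
    mti$confidence <- prediction$confidence[match(key, pkey)]
  }
  flag_join <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(rep(FALSE, nrow(mti)))
    key %in% paste(df$mirna, df$gene, sep = "\r")
  }
  mti$validated <- flag_join(clean_pairs(validated, "validated list"))
  mti$iclip <- flag_join(clean_pairs(iclip, "iCLIP list"))
  mti$human_dysregulated_mirna <- if (is.null(human_de_mirna))
    rep(FALSE, nrow(mti)) else human %in% human_de_mirna
  mti$human_dysregulated_mrna <- if (is.null(human_de_mrna))
    rep(FALSE, nrow(mti)) else mti$mrna %in% human_de_mrna
  mti
}

#' Confidence-class composition of a set of MTIs
#'
#' Proportion of interactions per confidence class, the comparison used to
#' ask whether network-inferred MTIs are enriched for higher-confidence
#' predicted interactions relative to all predictions for the same miRNAs.
#'
#' @param confidence character vector of confidence classes (`NA` = absent
#'   from the prediction resource).
#' @return named proportion table over Very High/High/Medium/Low/NA.
#' @export
confidence_profile <- function(confidence) {
  lev <- c("Very High", "High", "Medium", "Low")
  f <- factor(ifelse(is.na(confidence), "NA", confidence), levels = c(lev, "NA"))
  prop.table(table(f))
}
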