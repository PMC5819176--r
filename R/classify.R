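#' Select the representative isoform of a gene
#'
#' The longest protein isoform represents the gene; ties break to the
#' lexicographically smallest protein id so the choice is deterministic
#' under any input ordering.
#'
#' @param annotation a [GeneAnnotation-class] object.
#' @param geneId single gene id, or NULL for all genes.
#' @return Named character vector gene_id -> protein_id.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "c", start = 1, end = 9,
#'                 strand = "+")
#' p <- data.frame(protein_id = c("g1.p1", "g1.p2"), gene_id = "g1",
#'                 length = c(300, 450))
#' selectRepresentativeIsoform(GeneAnnotation(g, p))
#' @export
selectRepresentativeIsoform <- function(annotation, geneId = NULL) {
    iso <- as.data.frame(isoforms(annotation))
    if (!is.null(geneId)) {
        iso <- iso[iso$gene_id %in% geneId, , drop = FALSE]
        if (!nrow(iso))
            stopValidation("gene has no isoform of known length: ",
                           paste(geneId, collapse = ", "))
    }
    iso <- iso[order(iso$gene_id, -iso$length, iso$protein_id), ,
               drop = FALSE]
    iso <- iso[!duplicated(iso$gene_id), , drop = FALSE]
    setNames(iso$protein_id, iso$gene_id)
}

# vectorised exclusion-set membership
isExcludedDomain <- function(domainNames, exclusion = DomainExclusion()) {
    out <- domainNames %in% exclusion@exact
    for (pat in exclusion@substring)
        out <- out | grepl(pat, domainNames, fixed = TRUE)
    out
}

#' Is a protein an NLR?
#'
#' A protein is classified as an NLR when it carries at least one NB-ARC
#' (PF00931) hit with e-value below the relaxed cutoff.
#'
#' @param hits [DomainHitSet-class] or data.frame of hits for one protein.
#' @param thresholds an [NLRThresholds-class] object.
#' @return TRUE/FALSE (FALSE for an empty hit set).
#' @examples
#' classifyNLR(data.frame(protein_id = "p", domain_name = "NB-ARC",
#'                        aa_start = 1, aa_end = 300, evalue = 1e-50))
#' @export
classifyNLR <- function(hits, thresholds = NLRThresholds()) {
    h <- if (is(hits, "DomainHitSet")) domainHits(hits) else hits
    if (NROW(h) == 0L) return(FALSE)
    if (length(unique(h$protein_id)) > 1L)
        stopValidation("classifyNLR expects hits of a single protein")
    any(h$domain_name %in% nbarcNames &
        h$evalue < thresholds@idEvalueRelaxed)
}

#' Apply the NB-ARC alignment coverage filter
#'
#' Proteins aligned to the NB-ARC1-ARC2 model are retained when they cover
#' at least `nbarcCoverageMin` (default 70%) of the model columns. Coverage
#' is supplied, not computed here: either as an alignment
#' ([Biostrings::AAStringSet], gaps as '-' or '.') or as a data.frame with
#' columns `protein_id` and `covered_columns` plus `totalColumns`.
#'
#' @param coverage alignment or per-protein covered-column table.
#' @param thresholds an [NLRThresholds-class] object.
#' @param totalColumns total model columns (required for the tabular form;
#'   for an alignment it defaults to the alignment width).
#' @param proteins optional protein ids the table must be restricted to;
#'   rows for unknown proteins are a validation error.
#' @return List with `retained` (protein ids), `removed` (protein ids) and
#'   `coverage` (named fraction vector).
#' @export
nbarcCoverageFilter <- function(coverage, thresholds = NLRThresholds(),
                                totalColumns = NULL, proteins = NULL) {
    if (is(coverage, "AAStringSet") || is(coverage, "XStringSet")) {
        mat <- as.matrix(coverage)
        covered <- rowSums(mat != "-" & mat != ".")
        if (is.null(totalColumns)) totalColumns <- ncol(mat)
        ids <- sub("\\s.*$", "", rownames(mat))
    } else {
        cov <- as.data.frame(coverage)
        if (!all(c("protein_id", "covered_columns") %in% colnames(cov)))
            stopValidation("coverage table needs protein_id and ",
                           "covered_columns")
        if (is.null(totalColumns))
            stopValidation("totalColumns required with a coverage table")
        covered <- cov$covered_columns
        ids <- cov$protein_id
    }
    if (!is.null(proteins) && !all(ids %in% proteins))
        stopValidation("coverage row(s) for unknown protein: ",
                       paste(head(setdiff(ids, proteins), 5L),
                             collapse = ", "))
    frac <- setNames(covered / totalColumns, ids)
    keep <- frac >= thresholds@nbarcCoverageMin
    list(retained = ids[keep], removed = ids[!keep], coverage = frac)
}

#' Extract integrated domains of one NLR protein
#'
#' An integrated domain (ID) is any domain hit whose family is not in the
#' structural exclusion set (NB-ARC, LRR*, AAA*, TIR, RPW8). Two nested
#' sets are returned: strict (e-value < 0.001) and relaxed
#' (e-value < 0.05). Hit positions are preserved for downstream
#' architecture profiling; overlapping hits of the same family are merged.
#'
#' @param hits [DomainHitSet-class] or data.frame of hits for one protein.
#' @param exclusion a [DomainExclusion-class] object.
#' @param thresholds an [NLRThresholds-class] object.
#' @return List with `strict` and `relaxed` (sorted unique family names,
#'   strict always a subset of relaxed) and `hits` (retained relaxed hits,
#'   merged per family, with a `tier` column).
#' @examples
#' h <- data.frame(protein_id = "p",
#'                 domain_name = c("NB-ARC", "LRR_8", "WRKY"),
#'                 aa_start = c(150, 500, 900),
#'                 aa_end = c(450, 560, 980),
#'                 evalue = c(1e-50, 1e-5, 1e-10))
#' extractIntegratedDomains(h)$strict
#' @export
extractIntegratedDomains <- function(hits, exclusion = DomainExclusion(),
                                     thresholds = NLRThresholds()) {
    h <- as.data.frame(if (is(hits, "DomainHitSet")) domainHits(hits) else hits)
    if (nrow(h) && length(unique(h$protein_id)) > 1L)
        stopValidation("extractIntegratedDomains expects a single protein")
    h <- h[!isExcludedDomain(h$domain_name, exclusion) &
           h$evalue < thresholds@idEvalueRelaxed, , drop = FALSE]
    strict <- sort(unique(h$domain_name[h$evalue <
                                        thresholds@idEvalueStrict]))
    relaxed <- sort(unique(h$domain_name))
    merged <- mergeFamilyHits(h)
    if (nrow(merged))
        merged$tier <- ifelse(merged$domain_name %in% strict,
                              "strict", "relaxed")
    list(strict = strict, relaxed = relaxed, hits = merged)
}

# merge overlapping hits of the same family on the same protein; distinct
# families are never merged
mergeFamilyHits <- function(h) {
    h <- as.data.frame(h)
    if (!nrow(h)) {
        h$tier <- character(0)
        return(h)
    }
    key <- paste(h$protein_id, h$domain_name, sep = "\r")
    parts <- lapply(split(seq_len(nrow(h)), key), function(i) {
        red <- IRanges::reduce(IRanges(h$aa_start[i], h$aa_end[i]))
        data.frame(protein_id = h$protein_id[i[1L]],
                   domain_name = h$domain_name[i[1L]],
                   aa_start = start(red), aa_end = end(red),
                   evalue = min(h$evalue[i]))
    })
    out <- do.call(rbind, parts)
    out <- out[order(out$protein_id, out$aa_start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify every gene of an annotation set
#'
#' Builds the per-gene NLR record table: representative isoform, NLR
#' status, NB-ARC alignment coverage (when supplied), the strict and
#' relaxed integrated-domain sets, and the clade label (when a partition
#' is supplied).
#'
#' @param annotation a [GeneAnnotation-class] object.
#' @param hits a [DomainHitSet-class] of all proteins.
#' @param thresholds an [NLRThresholds-class] object.
#' @param exclusion a [DomainExclusion-class] object.
#' @param coverage optional named coverage-fraction vector
#'   (see [nbarcCoverageFilter()], element `coverage`).
#' @param partition optional [CladePartition-class]; tips must be protein
#'   ids.
#' @param species optional single species label or named vector
#'   gene_id -> species.
#' @return DataFrame with one row per gene: gene_id, protein_id, is_nlr,
#'   nbarc_coverage, ids_strict, ids_relaxed (CharacterList), clade,
#'   species.
#' @export
classifyNLRSet <- function(annotation, hits, thresholds = NLRThresholds(),
                           exclusion = DomainExclusion(), coverage = NULL,
                           partition = NULL, species = NA_character_) {
    rep <- selectRepresentativeIsoform(annotation)
    h <- as.data.frame(domainHits(hits))
    h <- h[h$protein_id %in% rep, , drop = FALSE]
    iso <- isoforms(annotation)
    plen <- setNames(iso$length, iso$protein_id)
    over <- h$aa_end > plen[h$protein_id]
    if (any(over, na.rm = TRUE))
        stopValidation("domain hit(s) beyond protein length: ",
                       paste(head(unique(h$protein_id[which(over)]), 5L),
                             collapse = ", "))
    nlrProt <- unique(h$protein_id[h$domain_name %in% nbarcNames &
                                   h$evalue < thresholds@idEvalueRelaxed])
    hid <- h[!isExcludedDomain(h$domain_name, exclusion) &
             h$evalue < thresholds@idEvalueRelaxed &
             h$protein_id %in% nlrProt, , drop = FALSE]
    prot <- factor(hid$protein_id, levels = unname(rep))
    strictL <- lapply(split(hid$domain_name[hid$evalue <
                                            thresholds@idEvalueStrict],
                            prot[hid$evalue < thresholds@idEvalueStrict]),
                      function(x) sort(unique(x)))
    relaxL <- lapply(split(hid$domain_name, prot),
                     function(x) sort(unique(x)))
    out <- DataFrame(gene_id = names(rep), protein_id = unname(rep))
    out$is_nlr <- out$protein_id %in% nlrProt
    out$nbarc_coverage <- if (is.null(coverage)) NA_real_ else
        unname(coverage[out$protein_id])
    out$ids_strict <- CharacterList(strictL[out$protein_id])
    out$ids_relaxed <- CharacterList(relaxL[out$protein_id])
    out$clade <- if (is.null(partition)) NA_character_ else
        unname(cladeOf(partition)[out$protein_id])
    out$species <- if (length(species) == 1L) species else
        unname(species[out$gene_id])
    rownames(out) <- NULL
    out
}

#' Census of NLRs and NLR-IDs per species and clade
#'
#' Mirrors the published census layout: per species and clade, the number
#' of NLRs, the number carrying at least one integrated domain, and the
#' percentage (two decimals, truncated — the convention of the printed
#' tables). Both the strict and the relaxed tier are reported, plus an
#' all-clades row per species.
#'
#' @param records classification DataFrame from [classifyNLRSet()].
#' @return data.frame with columns species, clade, n_nlr, n_id_strict,
#'   pct_id_strict, n_id_relaxed, pct_id_relaxed.
#' @export
summarizeNLRIDCensus <- function(records) {
    r <- records[records$is_nlr, , drop = FALSE]
    sp <- ifelse(is.na(r$species), "all", as.character(r$species))
    cl <- ifelse(is.na(r$clade), "unassigned", as.character(r$clade))
    hasS <- lengths(r$ids_strict) > 0L
    hasR <- lengths(r$ids_relaxed) > 0L
    oneBlock <- function(sp, cl, hasS, hasR) {
        key <- paste(sp, cl, sep = "\r")
        agg <- function(x) as.vector(tapply(x, key, sum))
        u <- !duplicated(key)
        data.frame(species = sp[u][order(key[u])],
                   clade = cl[u][order(key[u])],
                   n_nlr = agg(rep(1L, length(key))),
                   n_id_strict = agg(as.integer(hasS)),
                   n_id_relaxed = agg(as.integer(hasR)))
    }
    per <- oneBlock(sp, cl, hasS, hasR)
    tot <- oneBlock(sp, rep("all", length(sp)), hasS, hasR)
    out <- rbind(per, tot)
    out$pct_id_strict <- pctTrunc(out$n_id_strict, out$n_nlr)
    out$pct_id_relaxed <- pctTrunc(out$n_id_relaxed, out$n_nlr)
    out <- out[order(out$species, out$clade != "all", out$clade),
               c("species", "clade", "n_nlr", "n_id_strict",
                 "pct_id_strict", "n_id_relaxed", "pct_id_relaxed")]
    rownames(out) <- NULL
    out
}
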