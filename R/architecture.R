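#' Extract unannotated protein regions
#'
#' Merges all domain intervals (any family, any e-value tier — region
#' extraction must be annotation-free) and returns the complement within
#' [1, L], keeping segments of at least `minRegionLen` amino acids
#' (default 20). These are the regions submitted to de novo motif
#' discovery.
#'
#' @param proteinLength protein length in aa.
#' @param hits [DomainHitSet-class] or data.frame of hits for one protein
#'   (may be empty).
#' @param thresholds an [NLRThresholds-class] object (`minRegionLen`).
#' @return An [IRanges::IRanges] of disjoint, sorted regions.
#' @examples
#' extractUnannotatedRegions(100, data.frame(protein_id = "p",
#'     domain_name = "X", aa_start = 10, aa_end = 50, evalue = 1e-9))
#' @export
extractUnannotatedRegions <- function(proteinLength, hits,
                                      thresholds = NLRThresholds()) {
    L <- as.integer(proteinLength)
    if (is.na(L) || L < 1L)
        stopValidation("protein length must be a positive integer")
    h <- as.data.frame(if (is(hits, "DomainHitSet")) domainHits(hits) else hits)
    if (nrow(h) && any(h$aa_end > L))
        stopValidation("domain hit beyond protein length")
    dom <- IRanges::reduce(IRanges(h$aa_start, h$aa_end))
    gaps <- IRanges::setdiff(IRanges(1L, L), dom)
    gaps[width(gaps) >= thresholds@minRegionLen]
}

# map a domain family name onto the profile element vocabulary
profileLabel <- function(domainNames) {
    out <- rep("ID", length(domainNames))
    out[domainNames %in% nbarcNames] <- "NB"
    out[grepl("LRR", domainNames, fixed = TRUE)] <- "LRR"
    out[domainNames %in% c("Rx_N", "CC", "Coiled-coil")] <- "CC"
    out
}

#' Normalised domain-position profile of a protein
#'
#' Normalises the protein length to 1.0 and places every domain and motif
#' at the normalised midpoint of its interval,
#' `((start + end) / 2) / length` — the representation used to compare
#' architectures across NLRs of different lengths. Domain families are
#' mapped onto the element vocabulary CC / NB / LRR / ID; motifs keep
#' their motif id.
#'
#' @param proteinLength protein length in aa (> 0).
#' @param hits [DomainHitSet-class] or data.frame of domain hits for one
#'   protein.
#' @param motifs optional data.frame/DataFrame of motif hits for the same
#'   protein (columns motif_id, aa_start, aa_end).
#' @return data.frame with columns label, aa_start, aa_end, midpoint,
#'   ordered by midpoint.
#' @examples
#' normalizedProfile(1000, data.frame(protein_id = "p",
#'     domain_name = "WRKY", aa_start = 100, aa_end = 200, evalue = 1e-9))
#' @export
normalizedProfile <- function(proteinLength, hits, motifs = NULL) {
    L <- as.numeric(proteinLength)
    if (is.na(L) || L <= 0) stopValidation("protein length must be > 0")
    h <- as.data.frame(if (is(hits, "DomainHitSet")) domainHits(hits) else hits)
    prof <- data.frame(label = profileLabel(h$domain_name),
                       aa_start = h$aa_start, aa_end = h$aa_end)
    if (!is.null(motifs) && NROW(motifs)) {
        m <- as.data.frame(motifs)
        prof <- rbind(prof, data.frame(label = m$motif_id,
                                       aa_start = m$aa_start,
                                       aa_end = m$aa_end))
    }
    if (nrow(prof) && any(prof$aa_end > L))
        stopValidation("element beyond protein length")
    prof$midpoint <- (prof$aa_start + prof$aa_end) / 2 / L
    prof <- prof[order(prof$midpoint, prof$label), , drop = FALSE]
    rownames(prof) <- NULL
    prof
}

#' Is the CID motif immediately upstream of the integration site?
#'
#' For every (CID motif, integrated-domain) pair on a protein, tests the
#' placement observed at the integration site: the motif must end at or
#' before the ID start, with an intervening gap of at most `cidWindow`
#' amino acids (default 50). The gap is `ID.aa_start - CID.aa_end - 1`.
#'
#' @param motifs data.frame/DataFrame of motif hits for one protein; rows
#'   with `motif_id == cidMotif` are used.
#' @param idHits data.frame of retained integrated-domain hits for the
#'   same protein (e.g. `extractIntegratedDomains(...)$hits`).
#' @param thresholds an [NLRThresholds-class] object (`cidWindow`).
#' @param cidMotif motif id of the conserved integration-site motif.
#' @return data.frame with one row per (CID, ID) pair: cid_start, cid_end,
#'   id_domain, id_start, id_end, gap_aa, immediately_upstream. Zero rows
#'   when the protein lacks a CID motif or an ID.
#' @export
cidUpstreamOfID <- function(motifs, idHits, thresholds = NLRThresholds(),
                            cidMotif = "CID") {
    m <- as.data.frame(motifs)
    m <- m[m$motif_id == cidMotif, , drop = FALSE]
    h <- as.data.frame(idHits)
    if (!nrow(m) || !nrow(h))
        return(data.frame(cid_start = integer(), cid_end = integer(),
                          id_domain = character(), id_start = integer(),
                          id_end = integer(), gap_aa = integer(),
                          immediately_upstream = logical()))
    grid <- expand.grid(i = seq_len(nrow(m)), j = seq_len(nrow(h)))
    gap <- h$aa_start[grid$j] - m$aa_end[grid$i] - 1L
    data.frame(cid_start = m$aa_start[grid$i],
               cid_end = m$aa_end[grid$i],
               id_domain = h$domain_name[grid$j],
               id_start = h$aa_start[grid$j],
               id_end = h$aa_end[grid$j],
               gap_aa = gap,
               immediately_upstream =
                   m$aa_end[grid$i] <= h$aa_start[grid$j] &
                   gap <= thresholds@cidWindow)
}

#' Motif presence/absence matrix with per-clade prevalence
#'
#' Boolean tips x motifs matrix relative to a clade partition, plus
#' per-clade counts and fractions — the summary used to superimpose motif
#' occurrence on the NB-ARC phylogeny. Motif hits on proteins absent from
#' the partition are skipped with a warning.
#'
#' @param motifs data.frame/DataFrame of motif hits (protein_id,
#'   motif_id).
#' @param partition a [CladePartition-class]; tips are protein ids.
#' @return List with `matrix` (logical, tips x motifs) and `prevalence`
#'   (data.frame clade, motif, n_with, n_tips, fraction).
#' @export
motifPresenceMatrix <- function(motifs, partition) {
    co <- cladeOf(partition)
    m <- as.data.frame(motifs)
    unknown <- !m$protein_id %in% names(co)
    if (any(unknown)) {
        warning("skipping ", sum(unknown),
                " motif hit(s) on unknown proteins")
        m <- m[!unknown, , drop = FALSE]
    }
    motifIds <- sort(unique(m$motif_id))
    mat <- matrix(FALSE, length(co), max(1L, length(motifIds)),
                  dimnames = list(names(co),
                                  if (length(motifIds)) motifIds else "none"))
    if (length(motifIds)) {
        mat <- matrix(FALSE, length(co), length(motifIds),
                      dimnames = list(names(co), motifIds))
        mat[cbind(m$protein_id, m$motif_id)] <- TRUE
    }
    clades <- sort(unique(co))
    prev <- expand.grid(clade = clades,
                        motif = colnames(mat),
                        stringsAsFactors = FALSE)
    prev$n_with <- mapply(function(cl, mo) sum(mat[co == cl, mo]),
                          prev$clade, prev$motif)
    prev$n_tips <- as.vector(table(factor(co, clades)))[
        match(prev$clade, clades)]
    prev$fraction <- ifelse(prev$n_tips == 0, 0,
                            prev$n_with / prev$n_tips)
    list(matrix = mat, prevalence = prev)
}
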