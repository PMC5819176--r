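#' Detect head-to-head tandem NLR gene pairs
#'
#' A tandem pair is an upstream NLR on the reverse strand followed by a
#' downstream NLR on the forward strand on the same sequence, with no
#' other annotated gene between them and an intergenic gap of at most
#' `tandemMaxGap` (default 15 kbp) — the sensor/helper arrangement typified
#' by RRS1/RPS4. The gap is `downstream.start - upstream.end - 1`,
#' compared inclusively. "No other gene" means no annotated gene of any
#' type intersects the open interval between the pair; a gene spanning the
#' whole gap also blocks it. Overlapping candidates
#' (upstream.end >= downstream.start) are rejected. Pairs never span
#' sequences. The scan is linear over position-sorted genes per sequence.
#'
#' @param annotation a [GeneAnnotation-class] object (all genes, not just
#'   NLRs: non-NLR genes act as blockers).
#' @param nlrGenes character vector of gene ids classified as NLRs.
#' @param thresholds an [NLRThresholds-class] object.
#' @return data.frame with columns upstream_gene, downstream_gene, chrom,
#'   gap_bp, ordered by (chrom, position).
#' @export
findTandemPairs <- function(annotation, nlrGenes,
                            thresholds = NLRThresholds()) {
    gr <- genes(annotation)
    if (length(bad <- setdiff(nlrGenes, names(gr))))
        stopValidation("NLR gene id(s) not in annotation: ",
                       paste(head(bad, 5L), collapse = ", "))
    ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
    gr <- gr[ord]
    chrom <- as.character(seqnames(gr))
    st <- start(gr); en <- end(gr)
    sd <- as.character(strand(gr))
    isNLR <- names(gr) %in% nlrGenes
    out <- list()
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        s <- st[i]; e <- en[i]; d <- sd[i]; n <- isNLR[i]
        ids <- names(gr)[i]
        m <- length(i)
        if (m < 2L) next
        # j[u]: last start-sorted index with start <= end of u, so the
        # next gene after u is j[u] + 1 and a blocker exists iff some
        # gene starting at or before end(u) extends beyond it
        j <- findInterval(e, s)
        cm <- cummax(e)
        blocked <- cm[j] > e
        u <- which(n & d == "-" & !blocked & j < m)
        if (!length(u)) next
        v <- j[u] + 1L
        # equal-start neighbours of the downstream gene are ambiguous
        ambiguous <- v < m & s[pmin(v + 1L, m)] == s[v]
        gap <- s[v] - e[u] - 1L
        keep <- !ambiguous & n[v] & d[v] == "+" &
            gap <= thresholds@tandemMaxGap
        if (any(keep))
            out[[length(out) + 1L]] <-
                data.frame(upstream_gene = ids[u[keep]],
                           downstream_gene = ids[v[keep]],
                           chrom = ch, gap_bp = gap[keep])
    }
    if (!length(out))
        return(data.frame(upstream_gene = character(),
                          downstream_gene = character(),
                          chrom = character(), gap_bp = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Classify tandem pairs by ID status and clade
#'
#' Adds the pair class (ID/ID, ID/NLR, NLR/ID, NLR/NLR — upstream member
#' first) and the clade pair, looked up from the classification records.
#'
#' @param pairs data.frame from [findTandemPairs()].
#' @param records classification DataFrame from [classifyNLRSet()].
#' @param tier `"strict"` (default) or `"relaxed"`: which ID set decides
#'   ID status.
#' @return `pairs` with extra columns class, upstream_clade,
#'   downstream_clade.
#' @export
classifyTandemPairs <- function(pairs, records,
                                tier = c("strict", "relaxed")) {
    tier <- match.arg(tier)
    col <- if (tier == "strict") "ids_strict" else "ids_relaxed"
    lab <- function(g) {
        i <- match(g, records$gene_id)
        if (anyNA(i))
            stopValidation("pair member without record: ",
                           paste(g[is.na(i)], collapse = ", "))
        ifelse(lengths(records[[col]][i]) > 0L, "ID", "NLR")
    }
    cl <- function(g) as.character(records$clade[match(g, records$gene_id)])
    pairs$class <- if (nrow(pairs))
        paste(lab(pairs$upstream_gene), lab(pairs$downstream_gene),
              sep = "/") else character(0)
    pairs$upstream_clade <- cl(pairs$upstream_gene)
    pairs$downstream_clade <- cl(pairs$downstream_gene)
    pairs
}

#' Build the tandem-vs-group 2x2 contingency table
#'
#' Cell a counts NLRs in the group that are tandem members, b group
#' singles, c non-group tandem members, d non-group singles; the four
#' cells always add up to the NLR census. A tandem member is any NLR gene
#' occurring in at least one pair (gene-level, deduplicated). Grouping is
#' either ID-bearing status or membership of a designated clade.
#'
#' @param records classification DataFrame from [classifyNLRSet()].
#' @param pairs data.frame from [findTandemPairs()].
#' @param grouping `"has_id"` or `"in_designated_clade"`.
#' @param designatedClade clade label for the clade grouping.
#' @param tier `"strict"` (default) or `"relaxed"` ID set.
#' @return A [ContingencyResult-class] with the Fisher test applied.
#' @export
buildContingency <- function(records, pairs,
                             grouping = c("has_id", "in_designated_clade"),
                             designatedClade = "C16",
                             tier = c("strict", "relaxed")) {
    grouping <- match.arg(grouping)
    tier <- match.arg(tier)
    r <- records[records$is_nlr, , drop = FALSE]
    tandem <- r$gene_id %in% c(pairs$upstream_gene, pairs$downstream_gene)
    grp <- if (grouping == "has_id") {
        col <- if (tier == "strict") "ids_strict" else "ids_relaxed"
        lengths(r[[col]]) > 0L
    } else {
        if (!designatedClade %in% r$clade)
            stopValidation("unknown designated clade: ", designatedClade)
        !is.na(r$clade) & r$clade == designatedClade
    }
    ContingencyResult(sum(grp & tandem), sum(grp & !tandem),
                      sum(!grp & tandem), sum(!grp & !tandem))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the conventional two-sided exact p-value by summing, over the
#' hypergeometric distribution with the table's margins, the
#' probabilities of all tables at most as probable as the observed one
#' (with the usual 1 + 1e-7 relative tie tolerance). The odds ratio
#' reported is the sample cross-product ratio a*d/(b*c), infinite when
#' only b*c is zero.
#'
#' @param a a [ContingencyResult-class], a 2x2 matrix, or the first cell.
#' @param b,c,d remaining cells when `a` is a count.
#' @return For a [ContingencyResult-class] input, the object with
#'   `pValue` and `oddsRatio` filled; otherwise a named list
#'   `list(p.value, odds.ratio)`.
#' @examples
#' fisherExact2x2(50, 365, 268, 5511)$p.value   # 1.02e-08
#' @export
fisherExact2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is(a, "ContingencyResult")) {
        ct <- counts(a)
        res <- fisherCore(ct[1L, 1L], ct[1L, 2L], ct[2L, 1L], ct[2L, 2L])
        a@pValue <- res$p.value
        a@oddsRatio <- res$odds.ratio
        validObject(a)
        return(a)
    }
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == c(2L, 2L)))
        return(fisherCore(a[1L, 1L], a[1L, 2L], a[2L, 1L], a[2L, 2L]))
    }
    fisherCore(a, b, c, d)
}

fisherCore <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    m <- a + b; n <- c + d; k <- a + c
    if (m + n == 0L) return(list(p.value = 1, odds.ratio = NA_real_))
    x <- max(0L, k - n):min(k, m)
    dens <- dhyper(x, m, n, k)
    pObs <- dhyper(a, m, n, k)
    p <- min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
    orr <- if (b * c > 0) (a * d) / (b * c)
           else if (a * d > 0) Inf else NA_real_
    list(p.value = p, odds.ratio = orr)
}

#' Clade-pairing matrix of tandem pairs
#'
#' Counts pairs by (upstream clade, downstream clade); the pattern behind
#' the observation that sensor-clade NLRs pair with a single helper clade.
#'
#' @param pairs data.frame from [findTandemPairs()], clade columns added
#'   by [classifyTandemPairs()] or supplied directly.
#' @param partition optional [CladePartition-class]; used together with
#'   `records` when the pair table lacks clade columns.
#' @param records optional classification DataFrame (protein/gene join).
#' @return k x k integer matrix with clade labels on both dimensions;
#'   row plus column sums equal the pair count.
#' @export
cladePairingMatrix <- function(pairs, partition = NULL, records = NULL) {
    if (!all(c("upstream_clade", "downstream_clade") %in% colnames(pairs))) {
        if (is.null(records))
            stopValidation("need clade columns or a records table")
        pairs <- classifyTandemPairs(pairs, records)
    }
    labs <- sort(unique(c(pairs$upstream_clade, pairs$downstream_clade,
                          if (!is.null(partition)) cladeOf(partition))))
    labs <- labs[!is.na(labs)]
    mat <- matrix(0L, length(labs), length(labs),
                  dimnames = list(upstream = labs, downstream = labs))
    if (nrow(pairs)) {
        tab <- table(factor(pairs$upstream_clade, levels = labs),
                     factor(pairs$downstream_clade, levels = labs))
        mat[] <- as.integer(tab)
    }
    mat
}

#' Per-clade transposable-element overlap fractions
#'
#' Fraction of member genes overlapping at least one TE interval by at
#' least 1 bp (closed intervals: an interval starting one bp after a gene
#' ends does not overlap). Intervals on sequences absent from the
#' annotation are skipped with a warning.
#'
#' @param annotation a [GeneAnnotation-class] object.
#' @param teIntervals [GenomicRanges::GRanges] of TE coordinates (1-based
#'   closed, as returned by [readBedIntervals()]).
#' @param cladeByGene named character vector gene_id -> clade label.
#' @return data.frame with columns clade, n_genes, n_overlapping,
#'   fraction.
#' @export
teOverlapSummary <- function(annotation, teIntervals, cladeByGene) {
    gr <- genes(annotation)
    gr <- gr[names(gr) %in% names(cladeByGene)]
    unk <- !as.character(seqnames(teIntervals)) %in%
        unique(as.character(seqnames(gr)))
    if (any(unk)) {
        warning("skipping ", sum(unk),
                " TE interval(s) on unknown sequences")
        teIntervals <- teIntervals[!unk]
    }
    hit <- if (length(teIntervals))
        overlapsAny(gr, teIntervals, ignore.strand = TRUE)
    else rep(FALSE, length(gr))
    cl <- cladeByGene[names(gr)]
    clades <- sort(unique(cl))
    out <- data.frame(
        clade = clades,
        n_genes = as.vector(table(factor(cl, clades))),
        n_overlapping = as.vector(tapply(hit, factor(cl, clades), sum)))
    out$n_overlapping[is.na(out$n_overlapping)] <- 0L
    out$fraction <- ifelse(out$n_genes == 0, 0,
                           out$n_overlapping / out$n_genes)
    out
}
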