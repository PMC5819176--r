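# shared fixtures and independent oracles, built in code

# small annotation straight from vectors
makeAnn <- function(gene_id, chrom, start, end, strand,
                    protein_len = NULL) {
    if (is.null(protein_len)) protein_len <- rep(300L, length(gene_id))
    GeneAnnotation(
        data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand),
        data.frame(protein_id = paste0(gene_id, ".p1"),
                   gene_id = gene_id, length = protein_len))
}

hitRow <- function(protein, domain, s, e, ev) {
    data.frame(protein_id = protein, domain_name = domain,
               aa_start = s, aa_end = e, evalue = ev)
}

# brute-force oracle over all ordered gene pairs (the stated tandem
# detection oracle; quadratic, independent of the linear scan)
bruteTandemPairs <- function(ann, nlr, maxGap = 15000) {
    gr <- genes(ann)
    df <- data.frame(id = names(gr),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     s = GenomicRanges::start(gr),
                     e = GenomicRanges::end(gr),
                     d = as.character(GenomicRanges::strand(gr)))
    res <- character(0)
    for (ch in unique(df$chrom)) {
        x <- df[df$chrom == ch, ]
        for (a in seq_len(nrow(x))) for (b in seq_len(nrow(x))) {
            if (a == b) next
            u <- x[a, ]; v <- x[b, ]
            if (!(u$id %in% nlr && v$id %in% nlr)) next
            if (u$d != "-" || v$d != "+") next
            if (u$e >= v$s) next
            if (v$s - u$e - 1 > maxGap) next
            others <- x[-c(a, b), ]
            if (nrow(others) &&
                any(others$s <= v$s - 1 & others$e >= u$e + 1)) next
            res <- c(res, paste(u$id, v$id))
        }
    }
    sort(res)
}

pairKeys <- function(pairs)
    sort(paste(pairs$upstream_gene, pairs$downstream_gene))

# exhaustive fixed-margin enumeration oracle for the two-sided Fisher p:
# probabilities from first principles (binomial coefficients), summing
# all tables with probability <= the observed one (same tie tolerance
# convention as the conventional test)
fisherEnumOracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
    probs <- exp(logp)
    pObs <- probs[match(a, xs)]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# canonical form of a partition for unordered comparison
partitionBlocks <- function(x) {
    blocks <- lapply(split(names(cladeOf(x)), cladeOf(x)), sort)
    unname(blocks[order(vapply(blocks, `[`, "", 1L))])
}

tipBlocks <- function(lst) {
    blocks <- lapply(lst, sort)
    unname(blocks[order(vapply(blocks, `[`, "", 1L))])
}

plantedPartition <- function(sim) {
    tg <- sim$truth$genes
    tipBlocks(split(tg$protein_id[tg$is_nlr], tg$clade[tg$is_nlr]))
}
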