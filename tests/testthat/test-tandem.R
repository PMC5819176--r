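test_that("the head-to-head rule accepts and rejects as specified", {
    base <- function(strandA = "-", between = FALSE, gap = NULL) {
        endB <- if (is.null(gap)) 5000 else 3000 + gap + 1
        df <- data.frame(
            gene_id = c("A", "B", if (between) "X"),
            chrom = "chr1",
            start = c(1000, endB, if (between) 3500),
            end = c(3000, endB + 3000, if (between) 4000),
            strand = c(strandA, "+", if (between) "+"))
        makeAnn(df$gene_id, df$chrom, df$start, df$end, df$strand)
    }
    p <- findTandemPairs(base(), c("A", "B"))
    expect_equal(nrow(p), 1L)
    expect_equal(p$gap_bp, 1999L)
    expect_equal(c(p$upstream_gene, p$downstream_gene), c("A", "B"))

    expect_equal(nrow(findTandemPairs(base(strandA = "+"),
                                      c("A", "B"))), 0L)
    expect_equal(nrow(findTandemPairs(base(between = TRUE),
                                      c("A", "B"))), 0L)
    # gap boundary: 15000 accepted (inclusive), 15001 rejected
    expect_equal(nrow(findTandemPairs(base(gap = 15000), c("A", "B"))),
                 1L)
    expect_equal(nrow(findTandemPairs(base(gap = 15001), c("A", "B"))),
                 0L)
    # overlapping candidates are rejected
    ov <- makeAnn(c("A", "B"), "chr1", c(1000, 2500), c(3000, 6000),
                  c("-", "+"))
    expect_equal(nrow(findTandemPairs(ov, c("A", "B"))), 0L)
    # a gene fully containing the gap blocks the pair
    cont <- makeAnn(c("A", "B", "W"), "chr1", c(1000, 5000, 500),
                    c(3000, 8000, 4800), c("-", "+", "+"))
    expect_equal(nrow(findTandemPairs(cont, c("A", "B"))), 0L)
})

test_that("planted pairs are recovered exactly with the negatives rejected", {
    sim <- simulateDataset(SimulationConfig(seed = 51, tandemRate = 0.1),
                           what = c("annotation", "domains"))
    tg <- sim$truth$genes
    nlr <- tg$gene_id[tg$is_nlr]
    found <- findTandemPairs(sim$annotation, nlr)
    expect_identical(pairKeys(found), pairKeys(sim$truth$pairs))
    # the three near-miss negatives are present and rejected
    expect_setequal(
        unique(tg$unit_type[tg$is_nlr & !tg$tandem &
                            grepl("^neg", tg$unit_type)]),
        c("neg_strand", "neg_gap", "neg_between"))
    negGenes <- tg$gene_id[grepl("^neg", tg$unit_type)]
    expect_false(any(c(found$upstream_gene, found$downstream_gene) %in%
                     negGenes))
})

test_that("the linear scan equals the brute-force all-pairs oracle", {
    for (s in c(3, 12)) {
        sim <- simulateDataset(
            SimulationConfig(seed = s, nChromosomes = 2L,
                             genesPerChromosome = 80L,
                             nlrFraction = 0.35, tandemRate = 0.25),
            what = c("annotation", "domains"))
        nlr <- sim$truth$genes$gene_id[sim$truth$genes$is_nlr]
        expect_identical(
            pairKeys(findTandemPairs(sim$annotation, nlr)),
            bruteTandemPairs(sim$annotation, nlr))
    }
})

test_that("pair detection is shift- and shuffle-invariant, gap-monotone", {
    sim <- simulateDataset(SimulationConfig(seed = 52, tandemRate = 0.1),
                           what = c("annotation", "domains"))
    tg <- sim$truth$genes
    nlr <- tg$gene_id[tg$is_nlr]
    p0 <- findTandemPairs(sim$annotation, nlr)
    # uniform coordinate shift
    shifted <- makeAnn(tg$gene_id, tg$chrom, tg$start + 10000L,
                       tg$end + 10000L, tg$strand)
    expect_identical(pairKeys(findTandemPairs(shifted, nlr)),
                     pairKeys(p0))
    # record shuffling
    o <- sample(nrow(tg))
    shuffled <- makeAnn(tg$gene_id[o], tg$chrom[o], tg$start[o],
                        tg$end[o], tg$strand[o])
    expect_identical(pairKeys(findTandemPairs(shuffled, nlr)),
                     pairKeys(p0))
    # increasing the allowed gap never removes a pair
    narrow <- findTandemPairs(sim$annotation, nlr,
                              NLRThresholds(tandemMaxGap = 8000L))
    expect_true(all(pairKeys(narrow) %in% pairKeys(p0)))
})

test_that("contingency cells count tandem membership at gene level", {
    rec <- S4Vectors::DataFrame(
        gene_id = sprintf("g%02d", 1:10),
        protein_id = sprintf("g%02d.p", 1:10), is_nlr = TRUE)
    # 2 pairs (4 tandem genes), 3 IDs of which exactly 1 is paired
    rec$ids_strict <- IRanges::CharacterList(
        c(list("WRKY"), rep(list(character(0)), 3), list("B3"),
          list("AP2"), rep(list(character(0)), 4)))
    rec$ids_relaxed <- rec$ids_strict
    rec$clade <- c("C16", "C7", "C16", "C7", rep("C1", 6))
    pairs <- data.frame(upstream_gene = c("g01", "g03"),
                        downstream_gene = c("g02", "g04"),
                        chrom = "chr1", gap_bp = c(100L, 200L))
    ct <- buildContingency(rec, pairs, "has_id")
    expect_equal(as.vector(t(counts(ct))), c(1, 2, 3, 4))
    expect_equal(sum(counts(ct)), 10)

    # empty pair list
    ct0 <- buildContingency(rec, pairs[0, ], "has_id")
    expect_equal(as.vector(t(counts(ct0))), c(0, 3, 0, 7))

    # clade grouping
    ctc <- buildContingency(rec, pairs, "in_designated_clade",
                            designatedClade = "C16")
    expect_equal(as.vector(t(counts(ctc))), c(2, 0, 2, 6))
    expect_error(buildContingency(rec, pairs, "in_designated_clade",
                                  designatedClade = "C99"),
                 "unknown designated clade")
})

test_that("pair classes combine member ID status upstream-first", {
    rec <- S4Vectors::DataFrame(
        gene_id = c("u", "d"), protein_id = c("u.p", "d.p"),
        is_nlr = TRUE)
    rec$ids_strict <- IRanges::CharacterList(list("WRKY", character(0)))
    rec$ids_relaxed <- rec$ids_strict
    rec$clade <- c("C16", "C7")
    pairs <- data.frame(upstream_gene = "u", downstream_gene = "d",
                        chrom = "chr1", gap_bp = 10L)
    cp <- classifyTandemPairs(pairs, rec)
    expect_equal(cp$class, "ID/NLR")
    expect_equal(c(cp$upstream_clade, cp$downstream_clade),
                 c("C16", "C7"))
})

test_that("the exact test reproduces published and degenerate tables", {
    expect_equal(signif(fisherExact2x2(50, 365, 268, 5511)$p.value, 3),
                 1.02e-08)
    expect_equal(signif(fisherExact2x2(5, 14, 39, 314)$p.value, 3),
                 6.01e-02)
    expect_equal(fisherExact2x2(1, 0, 0, 1)$p.value, 1.0)
    expect_equal(fisherExact2x2(0, 0, 0, 0)$p.value, 1.0)
    expect_error(fisherExact2x2(-1, 0, 0, 1), "non-negative")
    expect_equal(fisherExact2x2(2, 0, 0, 3)$odds.ratio, Inf)
})

test_that("the exact test equals enumeration and the reference test", {
    set.seed(88)
    for (i in 1:60) {
        cells <- as.integer(rmultinom(1, sample(5:28, 1), rep(1, 4)))
        p <- fisherExact2x2(cells[1], cells[2], cells[3], cells[4])
        expect_equal(p$p.value,
                     fisherEnumOracle(cells[1], cells[2], cells[3],
                                      cells[4]),
                     tolerance = 1e-12)
        expect_equal(p$p.value,
                     stats::fisher.test(matrix(cells, 2))$p.value,
                     tolerance = 1e-9)
    }
})

test_that("the exact p is invariant to table transposition and swaps", {
    set.seed(89)
    for (i in 1:25) {
        x <- matrix(as.integer(sample(0:40, 4, replace = TRUE)), 2)
        p0 <- fisherExact2x2(x)$p.value
        expect_equal(fisherExact2x2(t(x))$p.value, p0, tolerance = 1e-12)
        expect_equal(fisherExact2x2(x[2:1, 2:1])$p.value, p0,
                     tolerance = 1e-12)
    }
})

test_that("contingency margins reconstruct the census on planted data", {
    sim <- simulateDataset(SimulationConfig(seed = 53),
                           what = c("annotation", "domains"))
    rec <- classifyNLRSet(sim$annotation, sim$domains)
    pairs <- findTandemPairs(sim$annotation, rec$gene_id[rec$is_nlr])
    ct <- buildContingency(rec, pairs, "has_id")
    expect_equal(sum(counts(ct)), sum(rec$is_nlr))
    expect_identical(counts(ct), sim$truth$contingency)
})

test_that("the clade-pairing matrix recovers planted sensor/helper links", {
    pairs <- data.frame(upstream_gene = c("a", "b", "c"),
                        downstream_gene = c("x", "y", "z"),
                        chrom = "chr1", gap_bp = 1L,
                        upstream_clade = "C16", downstream_clade = "C7")
    pm <- cladePairingMatrix(pairs)
    expect_equal(pm["C16", "C7"], 3L)
    expect_equal(sum(pm), 3L)
    expect_equal(sum(cladePairingMatrix(pairs[0, ])), 0L)

    sim <- simulateDataset(
        SimulationConfig(seed = 54, tandemRate = 0.2,
                         pairClades = c(upstream = "MIC1",
                                        downstream = "C7")),
        what = c("annotation", "domains"))
    tg <- sim$truth$genes
    rec <- classifyNLRSet(sim$annotation, sim$domains)
    rec$clade <- tg$clade[match(rec$gene_id, tg$gene_id)]
    pairs2 <- classifyTandemPairs(
        findTandemPairs(sim$annotation, rec$gene_id[rec$is_nlr]), rec)
    pm2 <- cladePairingMatrix(pairs2)
    expect_equal(pm2["MIC1", "C7"], sum(sim$truth$cladePairing))
    # the MIC1 -> C7 cell is the only nonzero one, as planted
    expect_equal(sum(pm2), pm2["MIC1", "C7"])
    expect_equal(sim$truth$cladePairing["MIC1", "C7"],
                 sum(sim$truth$cladePairing))
})

test_that("TE overlap uses closed-interval intersection per clade", {
    ann <- makeAnn(c("g1", "g2"), "chr1", c(100, 1000), c(200, 1200),
                   c("+", "-"))
    te <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(150, 201), c(250, 300)))
    res <- teOverlapSummary(ann, te, c(g1 = "C1", g2 = "C1"))
    expect_equal(res$n_overlapping, 1L)   # 150-250 overlaps; 201-300 not
    expect_equal(res$fraction, 0.5)
    # adjacency does not overlap
    te2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
    expect_equal(teOverlapSummary(ann, te2,
                                  c(g1 = "C1", g2 = "C1"))$n_overlapping,
                 0L)
    expect_warning(
        teOverlapSummary(ann, GenomicRanges::GRanges(
            "chrUn", IRanges::IRanges(1, 10)), c(g1 = "C1", g2 = "C1")),
        "unknown sequences")

    sim <- simulateDataset(
        SimulationConfig(seed = 55, teOverlap = list(clade = "MIC1",
                                                     rate = 0.3)),
        what = c("annotation", "domains"))
    tg <- sim$truth$genes
    cladeByGene <- setNames(tg$clade[tg$is_nlr], tg$gene_id[tg$is_nlr])
    res2 <- teOverlapSummary(sim$annotation, sim$te, cladeByGene)
    mic <- res2[res2$clade == "MIC1", ]
    expect_equal(mic$n_overlapping,
                 length(sim$truth$te$overlapping_genes))
    expect_equal(mic$fraction,
                 length(sim$truth$te$overlapping_genes) /
                     sim$truth$te$n_clade_genes)
    others <- res2[res2$clade != "MIC1", ]
    expect_true(all(others$n_overlapping == 0L))
})
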