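test_that("the longest isoform represents the gene, ties break by id", {
    g <- data.frame(gene_id = "g1", chrom = "c", start = 1, end = 9,
                    strand = "+")
    ann <- GeneAnnotation(g, data.frame(
        protein_id = c("g1.p1", "g1.p2"), gene_id = "g1",
        length = c(300L, 450L)))
    expect_equal(unname(selectRepresentativeIsoform(ann)), "g1.p2")

    ann1 <- GeneAnnotation(g, data.frame(protein_id = "g1.p1",
                                         gene_id = "g1", length = 200L))
    expect_equal(unname(selectRepresentativeIsoform(ann1)), "g1.p1")

    annT <- GeneAnnotation(g, data.frame(
        protein_id = c("g1.pB", "g1.pA"), gene_id = "g1",
        length = c(400L, 400L)))
    expect_equal(unname(selectRepresentativeIsoform(annT)), "g1.pA")
    # deterministic under input ordering
    annT2 <- GeneAnnotation(g, data.frame(
        protein_id = c("g1.pA", "g1.pB"), gene_id = "g1",
        length = c(400L, 400L)))
    expect_equal(selectRepresentativeIsoform(annT),
                 selectRepresentativeIsoform(annT2))
})

test_that("NLR status requires an NB-ARC hit below the relaxed cutoff", {
    expect_true(classifyNLR(hitRow("p", "NB-ARC", 150, 450, 1e-50)))
    expect_false(classifyNLR(hitRow("p", "WRKY", 10, 80, 1e-10)))
    h <- hitRow("p", "NB-ARC", 150, 450, 0.04)
    expect_true(classifyNLR(h, NLRThresholds()))          # 0.04 < 0.05
    expect_false(classifyNLR(h, NLRThresholds(idEvalueRelaxed = 1e-3,
                                              idEvalueStrict = 1e-3)))
    expect_false(classifyNLR(hitRow("p", "NB-ARC", 1, 2, 1e-9)[0, ]))
})

test_that("the 70% NB-ARC coverage filter applies at the boundary", {
    cov <- data.frame(protein_id = c("pLow", "pEdge", "pFull"),
                      covered_columns = c(230L, 237L, 338L))
    res <- nbarcCoverageFilter(cov, totalColumns = 338L)
    expect_equal(res$removed, "pLow")      # 230/338 = 0.680
    expect_setequal(res$retained, c("pEdge", "pFull"))  # 237/338 = 0.7012
    expect_equal(unname(res$coverage["pLow"]), 230 / 338)

    aln <- Biostrings::AAStringSet(c(pA = paste(rep("M", 10), collapse = ""),
                                     pB = "MMM-------"))
    res2 <- nbarcCoverageFilter(aln)
    expect_equal(res2$retained, "pA")
    expect_equal(res2$removed, "pB")
    expect_error(nbarcCoverageFilter(cov, totalColumns = 338L,
                                     proteins = c("pLow", "pEdge")),
                 "unknown protein")
})

test_that("integrated domains exclude the structural set at two tiers", {
    h <- rbind(hitRow("p", "NB-ARC", 150, 450, 1e-50),
               hitRow("p", "LRR_8", 500, 560, 1e-5),
               hitRow("p", "WRKY", 800, 870, 1e-10))
    r <- extractIntegratedDomains(h)
    expect_equal(r$strict, "WRKY")
    expect_equal(r$relaxed, "WRKY")

    h2 <- rbind(hitRow("p", "NB-ARC", 150, 450, 1e-50),
                hitRow("p", "AAA_22", 500, 560, 1e-4))
    r2 <- extractIntegratedDomains(h2)
    expect_length(r2$strict, 0)
    expect_length(r2$relaxed, 0)

    h3 <- rbind(hitRow("p", "NB-ARC", 150, 450, 1e-50),
                hitRow("p", "Exo70", 800, 900, 0.01))
    r3 <- extractIntegratedDomains(h3)
    expect_length(r3$strict, 0)
    expect_equal(r3$relaxed, "Exo70")
})

test_that("overlapping same-family hits merge; families never merge", {
    h <- rbind(hitRow("p", "WRKY", 800, 860, 1e-10),
               hitRow("p", "WRKY", 840, 900, 1e-8),
               hitRow("p", "B3", 850, 910, 1e-9))
    r <- extractIntegratedDomains(h)
    w <- r$hits[r$hits$domain_name == "WRKY", ]
    expect_equal(nrow(w), 1L)
    expect_equal(c(w$aa_start, w$aa_end), c(800L, 900L))
    expect_equal(nrow(r$hits), 2L)
})

test_that("strict IDs nest inside relaxed IDs on randomised tables", {
    set.seed(404)
    excl <- DomainExclusion()
    fams <- c("NB-ARC", "LRR_1", "LRR_8", "AAA_16", "TIR", "RPW8",
              "WRKY", "Exo70", "Pkinase", "B3", "GRAS")
    for (i in seq_len(200)) {
        k <- sample(1:8, 1)
        h <- data.frame(protein_id = "p",
                        domain_name = sample(fams, k, replace = TRUE),
                        aa_start = sample(1:900, k),
                        aa_end = 0L, evalue = 10^runif(k, -12, 1))
        h$aa_end <- h$aa_start + sample(20:80, k, replace = TRUE)
        r <- extractIntegratedDomains(h, excl)
        expect_true(all(r$strict %in% r$relaxed))
        got <- c(r$strict, r$relaxed)
        expect_false(any(got %in% c("NB-ARC", "TIR", "RPW8")))
        expect_false(any(grepl("LRR", got) | grepl("AAA", got)))
    }
})

test_that("shrinking the relaxed cutoff shrinks the relaxed set to strict", {
    set.seed(77)
    h <- data.frame(protein_id = "p",
                    domain_name = sample(c("WRKY", "Exo70", "B3", "AP2"),
                                         12, replace = TRUE),
                    aa_start = seq(10, 900, length.out = 12),
                    aa_end = seq(40, 930, length.out = 12),
                    evalue = 10^runif(12, -8, -0.5))
    cuts <- c(0.05, 0.02, 0.005, 0.001)
    prev <- NULL
    for (cut in cuts) {
        r <- extractIntegratedDomains(
            h, thresholds = NLRThresholds(idEvalueStrict = 1e-3,
                                          idEvalueRelaxed = cut))
        if (!is.null(prev)) expect_true(all(r$relaxed %in% prev))
        prev <- r$relaxed
    }
    rEnd <- extractIntegratedDomains(
        h, thresholds = NLRThresholds(idEvalueStrict = 1e-3,
                                      idEvalueRelaxed = 1e-3 + 1e-12))
    rBase <- extractIntegratedDomains(h)
    expect_setequal(rEnd$relaxed, rBase$strict)
})

test_that("classification on planted data has recall and precision 1", {
    sim <- simulateDataset(SimulationConfig(seed = 31),
                           what = c("annotation", "domains"))
    rec <- classifyNLRSet(sim$annotation, sim$domains)
    tg <- sim$truth$genes
    m <- match(tg$gene_id, rec$gene_id)
    expect_identical(rec$is_nlr[m], tg$is_nlr)
    expect_identical(
        unname(vapply(rec$ids_strict, paste, "", collapse = ",")[m]),
        tg$ids_strict)
    expect_identical(
        unname(vapply(rec$ids_relaxed, paste, "", collapse = ",")[m]),
        tg$ids_relaxed)
})

test_that("the census matches the generator and recomputes from counts", {
    sim <- simulateDataset(SimulationConfig(seed = 32),
                           what = c("annotation", "domains"))
    rec <- classifyNLRSet(sim$annotation, sim$domains,
                          species = "synthetic")
    tg <- sim$truth$genes
    rec$clade <- tg$clade[match(rec$gene_id, tg$gene_id)]
    cen <- summarizeNLRIDCensus(rec)
    # against generator bookkeeping, per clade
    truthByClade <- tapply(tg$ids_strict[tg$is_nlr] != "",
                           tg$clade[tg$is_nlr], sum)
    per <- cen[cen$clade != "all", ]
    expect_equal(per$n_id_strict,
                 as.vector(truthByClade[per$clade]))
    # percentages recompute exactly from their own count columns
    expect_equal(per$pct_id_strict,
                 floor(1e4 * per$n_id_strict / per$n_nlr + 1e-9) / 100)
    allRow <- cen[cen$clade == "all", ]
    expect_equal(allRow$n_nlr, sum(tg$is_nlr))
})

test_that("census arithmetic handles the printed-table conventions", {
    rec <- S4Vectors::DataFrame(gene_id = sprintf("g%02d", 1:20),
                                protein_id = sprintf("g%02d.p", 1:20),
                                is_nlr = TRUE,
                                nbarc_coverage = NA_real_)
    rec$ids_strict <- IRanges::CharacterList(
        c(rep(list("WRKY"), 5), rep(list(character(0)), 15)))
    rec$ids_relaxed <- rec$ids_strict
    rec$clade <- "C1"
    rec$species <- "sp"
    cen <- summarizeNLRIDCensus(rec)
    row <- cen[cen$clade == "C1", ]
    expect_equal(c(row$n_nlr, row$n_id_strict, row$pct_id_strict),
                 c(20, 5, 25.00))
    # 7 of 12: truncation, not rounding (58.33)
    rec2 <- rec[1:12, ]
    rec2$ids_strict <- IRanges::CharacterList(
        c(rep(list("B3"), 7), rep(list(character(0)), 5)))
    rec2$ids_relaxed <- rec2$ids_strict
    cen2 <- summarizeNLRIDCensus(rec2)
    expect_equal(cen2$pct_id_strict[cen2$clade == "C1"], 58.33)
    # no NLRs at all: empty census, no division error
    rec3 <- rec
    rec3$is_nlr <- FALSE
    expect_equal(nrow(summarizeNLRIDCensus(rec3)), 0L)
})
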