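# brute-force oracle for midpoint rooting: the root must sit half-way
# along the longest tip-to-tip path, and all tip-to-tip path lengths
# must be preserved
midpointOracleCheck <- function(before, after) {
    d0 <- ape::cophenetic.phylo(before)
    d1 <- ape::cophenetic.phylo(after)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d1 - d0)), 1e-9)
    depth <- ape::node.depth.edgelength(after)[seq_len(ape::Ntip(after))]
    expect_equal(max(depth), max(d0) / 2, tolerance = 1e-9)
}

test_that("midpoint rooting bisects the longest tip-to-tip path", {
    tr <- readSupportTree(text = "(A:1,(B:1,C:4):1);")  # A-C path = 6
    m <- midpointRoot(tr)
    midpointOracleCheck(tr, m)
    depth <- setNames(
        ape::node.depth.edgelength(m)[seq_len(3)], m$tip.label)
    expect_equal(unname(depth["A"]), 3, tolerance = 1e-9)
    expect_equal(unname(depth["C"]), 3, tolerance = 1e-9)

    # idempotence on an already-midpoint-rooted tree
    m2 <- midpointRoot(m)
    midpointOracleCheck(m, m2)
    expect_equal(sort(ape::cophenetic.phylo(m2)["A", ]),
                 sort(ape::cophenetic.phylo(m)["A", ]))

    two <- midpointRoot(readSupportTree(text = "(A:1,B:3);"))
    expect_equal(ape::node.depth.edgelength(two)[1:2], c(2, 2))

    zero <- readSupportTree(text = "((A:0,B:0):0,C:0);")
    expect_warning(midpointRoot(zero), "degenerate")
})

test_that("midpoint rooting keeps supports attached to their subtrees", {
    for (s in c(3, 11, 27)) {
        tr <- simulateTree(list(A = sprintf("a%02d", 1:8),
                                B = sprintf("b%02d", 1:8),
                                C = sprintf("c%02d", 1:8)), seed = s)
        m <- midpointRoot(tr)
        for (cl in c("A", "B", "C")) {
            tips <- grep(tolower(cl), m$tip.label, value = TRUE)
            nd <- ape::getMRCA(m, tips)
            sup <- nodeSupports(m)[nd - ape::Ntip(m)]
            expect_gte(sup, 95L)
        }
    }
})

test_that("the clade rule founds clades at supported deep nodes", {
    thr <- NLRThresholds()
    # two supported deep subtrees, one weak subtree: hand-computed
    # depths a* = 0.1+1.6+0.2 = 1.9 > 1.4; c* weakly supported
    nwk <- paste0("(((a1:0.2,a2:0.2)100:1.6,(b1:0.2,b2:0.2)100:1.6)",
                  "50:0.1,(c1:2.0,c2:2.0)40:0.1);")
    part <- partitionClades(readSupportTree(text = nwk), thr)
    co <- cladeOf(part)
    expect_equal(length(unique(co)), 3L)
    expect_equal(unname(co["a1"]), unname(co["a2"]))
    expect_equal(unname(co["b1"]), unname(co["b2"]))
    expect_false(co[["a1"]] == co[["b1"]])
    expect_equal(unname(co["c1"]), unname(co["c2"]))

    # rule never fires when every support is below the threshold
    nwk2 <- paste0("(((a1:0.2,a2:0.2)79:1.6,(b1:0.2,b2:0.2)60:1.6)",
                   "50:0.1,(c1:2.0,c2:2.0)40:0.1);")
    p2 <- partitionClades(readSupportTree(text = nwk2), thr)
    expect_equal(unique(unname(cladeOf(p2))), "C1")

    # unknown support (missing label) conservatively fails the rule
    nwk3 <- "(((a1:0.2,a2:0.2):1.6,(b1:0.2,b2:0.2)100:1.6)50:0.1,c1:2.0);"
    p3 <- partitionClades(readSupportTree(text = nwk3), thr)
    co3 <- cladeOf(p3)
    expect_false(co3[["a1"]] == co3[["b1"]])
    expect_equal(unname(co3["a1"]), unname(co3["c1"]))  # both residual
})

test_that("overrides take precedence and validate their tips", {
    nwk <- paste0("(((a1:0.2,a2:0.2)10:1.6,(b1:0.2,b2:0.2)10:1.6)",
                  "10:0.1,(c1:2.0,c2:2.0)10:0.1);")
    tr <- readSupportTree(text = nwk)
    part <- partitionClades(tr, overrides = list(
        MIC1 = c("a1", "a2"), C7 = c("b1", "b2"), C9 = c("c1", "c2")))
    co <- cladeOf(part)
    expect_setequal(unique(unname(co)), c("MIC1", "C7", "C9"))
    expect_equal(unname(co[c("a1", "a2")]), c("MIC1", "MIC1"))
    expect_error(partitionClades(tr, overrides = list(X = c("zz"))),
                 "unknown tip")
})

test_that("partitions are total and permutation-invariant", {
    tr <- simulateTree(list(A = sprintf("a%02d", 1:6),
                            B = sprintf("b%02d", 1:7),
                            C = sprintf("c%02d", 1:5)), seed = 9)
    part <- partitionClades(midpointRoot(tr))
    expect_equal(length(cladeOf(part)), ape::Ntip(tr))
    expect_equal(sum(table(cladeOf(part))), ape::Ntip(tr))

    # permute the newick representation: rotate every internal node
    rot <- tr
    for (nd in (ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode))
        rot <- tryCatch(ape::rotate(rot, nd), error = function(e) rot)
    rot <- readSupportTree(text = ape::write.tree(rot))
    p2 <- partitionClades(midpointRoot(rot))
    expect_identical(partitionBlocks(part), partitionBlocks(p2))
})

test_that("raising the support threshold coarsens generator partitions", {
    for (s in c(2, 8, 15)) {
        tr <- midpointRoot(simulateTree(
            list(A = sprintf("a%02d", 1:8), B = sprintf("b%02d", 1:8),
                 C = sprintf("c%02d", 1:8), D = sprintf("d%02d", 1:8)),
            seed = s, stemSupportRange = c(85L, 100L)))
        lo <- partitionClades(tr, NLRThresholds(supportMin = 80L))
        hi <- partitionClades(tr, NLRThresholds(supportMin = 95L))
        coLo <- cladeOf(lo); coHi <- cladeOf(hi)
        # every block of the finer partition stays inside one block of
        # the coarser partition
        for (bl in split(names(coLo), coLo))
            expect_equal(length(unique(coHi[bl])), 1L)
        expect_lte(length(unique(coHi)), length(unique(coLo)))
    }
})

test_that("clade summaries count IDs and their clade share", {
    sim <- simulateDataset(SimulationConfig(seed = 41))
    part <- partitionClades(midpointRoot(sim$tree))
    rec <- classifyNLRSet(sim$annotation, sim$domains, partition = part)
    recNLR <- rec[rec$is_nlr, ]
    cs <- cladeSummaries(part, recNLR)
    expect_equal(sum(cs$n_tips), sum(recNLR$is_nlr))
    tg <- sim$truth$genes
    # union of planted strict domains per clade is recovered
    want <- tapply(tg$ids_strict[tg$is_nlr], tg$clade[tg$is_nlr],
                   function(x) sort(unique(unlist(strsplit(x[x != ""],
                                                           ",")))))
    got <- lapply(
        setNames(cs$id_domains, cs$clade),
        function(x) sort(unlist(strsplit(x, ","))))
    blocksGot <- partitionBlocks(part)
    blocksWant <- plantedPartition(sim)
    expect_identical(blocksGot, blocksWant)
    # match clades by tip content, then compare domain unions
    tipsByGot <- split(names(cladeOf(part)), cladeOf(part))
    for (lab in names(tipsByGot)) {
        truthLab <- unique(tg$clade[match(tipsByGot[[lab]],
                                          tg$protein_id)])
        expect_length(truthLab, 1L)
        w <- want[[truthLab]]
        expect_identical(got[[lab]], if (is.null(w)) character(0) else w)
    }
    # shares sum to 100 (up to truncation) and pct recomputes
    expect_equal(cs$pct_with_id,
                 floor(1e4 * cs$n_with_id / cs$n_tips + 1e-9) / 100)
    expect_error(cladeSummaries(part, recNLR[-1, ]), "without")
})

test_that("clade summary percentages follow the printed convention", {
    co <- setNames(rep("C16", 12), sprintf("t%02d", 1:12))
    part <- new("CladePartition", cladeOf = co, ruleParams = list(),
                foundingNodes = integer(0))
    rec <- S4Vectors::DataFrame(
        gene_id = sprintf("g%02d", 1:12),
        protein_id = sprintf("t%02d", 1:12), is_nlr = TRUE)
    rec$ids_strict <- IRanges::CharacterList(
        c(rep(list("WRKY"), 7), rep(list(character(0)), 5)))
    rec$ids_relaxed <- rec$ids_strict
    cs <- cladeSummaries(part, rec)
    expect_equal(c(cs$n_tips, cs$n_with_id, cs$pct_with_id),
                 c(12, 7, 58.33))
})
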