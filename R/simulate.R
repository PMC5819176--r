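#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' statistical structure of the grass NLR complement: a minority of genes
#' are NLRs; one clade (here labelled MIC1) carries integrated domains at
#' a high rate (~58%) while the complement-wide rate is ~10%; about 5% of
#' NLRs sit in head-to-head tandem pairs within 15 kbp; ID families are
#' drawn from the families observed as integrations (WRKY, kinases, Exo70,
#' B3, AP2, ...). Intergenic gaps between unrelated neighbours are drawn
#' above the pairing distance so the planted pairs are exactly the true
#' pairs; near-miss negatives (wrong strand, gap one bp over the limit, an
#' intervening gene) are planted to exercise every rejection branch of
#' the detector.
#'
#' @param seed integer seed; mandatory, threaded through all sampling.
#' @param nChromosomes number of chromosomes.
#' @param genesPerChromosome genes per chromosome (approximate: multi-gene
#'   units are never split across chromosomes).
#' @param nlrFraction fraction of genes that are NLRs.
#' @param cladeSpec data.frame(clade, fraction, idRate): clade labels,
#'   share of NLR tips, and per-clade probability that an NLR carries a
#'   strict integrated domain. Fractions must sum to 1. NULL for the
#'   default six-clade structure.
#' @param tandemRate fraction of NLR genes that are members of planted
#'   valid head-to-head pairs.
#' @param targetOddsRatio planted odds ratio between ID status and tandem
#'   membership: a tandem member's ID odds are its clade's baseline odds
#'   multiplied by this factor (1 = no association).
#' @param pairClades optional c(upstream =, downstream =) clade labels
#'   forced on planted pair members (the sensor/helper pattern); NULL for
#'   unconstrained.
#' @param intergenicGapRange bp gap range between unrelated neighbours
#'   (kept above tandemMaxGap + 1 so no accidental pairs arise).
#' @param pairGapRange bp gap range within planted pairs (<= 15000).
#' @param geneLengthRange,nlrGeneLengthRange gene length ranges in bp
#'   (rounded down to a codon multiple; protein length = bp/3 - 1).
#' @param idDomainPool Pfam family names used as integrated domains.
#' @param decoyRelaxedRate probability an NLR gets a decoy ID hit with
#'   e-value between the strict and relaxed cutoffs (relaxed-only ID).
#' @param decoyWeakRate probability of a decoy hit above the relaxed
#'   cutoff (never an ID).
#' @param plantNegatives plant the three near-miss pair negatives.
#' @param motifSpec list of motif plans; each is
#'   list(motif, clade, rate, length, gapRange) — `gapRange` (aa) places
#'   the motif that many residues upstream of the ID integration site,
#'   absent `gapRange` places it upstream of the NB-ARC domain.
#' @param teOverlap optional list(clade =, rate =): plant TE intervals
#'   overlapping that fraction of the clade's genes.
#' @return A list of class `"SimulationConfig"` with validated fields.
#' @export
SimulationConfig <- function(seed,
                             nChromosomes = 4L,
                             genesPerChromosome = 250L,
                             nlrFraction = 0.10,
                             cladeSpec = NULL,
                             tandemRate = 0.05,
                             targetOddsRatio = 1.0,
                             pairClades = NULL,
                             intergenicGapRange = c(16000L, 30000L),
                             pairGapRange = c(200L, 15000L),
                             geneLengthRange = c(1800L, 6000L),
                             nlrGeneLengthRange = c(2700L, 6000L),
                             idDomainPool = c("WRKY", "Exo70", "Pkinase",
                                              "B3", "AP2", "GRAS",
                                              "Kelch_1", "NPR1_like_C",
                                              "Pkinase_Tyr",
                                              "Myb_DNA-binding"),
                             decoyRelaxedRate = 0.15,
                             decoyWeakRate = 0.15,
                             plantNegatives = TRUE,
                             motifSpec = list(
                                 cid = list(motif = "CID", clade = "MIC1",
                                            rate = 0.7, length = 43L,
                                            gapRange = c(0L, 40L)),
                                 linker = list(motif = "I09",
                                               clade = "MIC1", rate = 0.5,
                                               length = 29L)),
                             teOverlap = NULL) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        stop("config error: seed is mandatory")
    if (is.null(cladeSpec))
        cladeSpec <- data.frame(
            clade = c("MIC1", "C15", "C13", "C7", "C1", "C2"),
            fraction = c(0.10, 0.10, 0.10, 0.20, 0.25, 0.25),
            idRate = c(0.58, 0.13, 0.00, 0.05, 0.08, 0.05))
    rates <- c(nlrFraction, tandemRate, cladeSpec$idRate)
    if (any(rates < 0 | rates > 1))
        stop("config error: rates must lie in [0, 1]")
    if (abs(sum(cladeSpec$fraction) - 1) > 1e-8)
        stop("config error: clade fractions must sum to 1")
    if (targetOddsRatio <= 0)
        stop("config error: targetOddsRatio must be positive")
    if (intergenicGapRange[1L] <= 15001L)
        stop("config error: intergenic gaps must exceed the pairing ",
             "distance so only planted pairs are valid")
    cfg <- list(seed = as.integer(seed),
                nChromosomes = as.integer(nChromosomes),
                genesPerChromosome = as.integer(genesPerChromosome),
                nlrFraction = nlrFraction, cladeSpec = cladeSpec,
                tandemRate = tandemRate,
                targetOddsRatio = targetOddsRatio,
                pairClades = pairClades,
                intergenicGapRange = as.integer(intergenicGapRange),
                pairGapRange = as.integer(pairGapRange),
                geneLengthRange = as.integer(geneLengthRange),
                nlrGeneLengthRange = as.integer(nlrGeneLengthRange),
                idDomainPool = idDomainPool,
                decoyRelaxedRate = decoyRelaxedRate,
                decoyWeakRate = decoyWeakRate,
                plantNegatives = isTRUE(plantNegatives),
                motifSpec = motifSpec, teOverlap = teOverlap)
    class(cfg) <- "SimulationConfig"
    cfg
}

# integer sampling helper that is safe for length-1 ranges
sampleRange <- function(lo, hi, n) {
    if (lo >= hi) rep(as.integer(lo), n)
    else as.integer(lo + floor(runif(n) * (hi - lo + 1)))
}

#' Simulate a dataset with known ground truth
#'
#' Generates a miniature annotated genome (GFF3-compatible gene models),
#' a Pfam-style domain-hit table, a clade-structured NB-ARC support tree,
#' a motif-hit table and optional TE intervals, together with the ground
#' truth of everything planted: per-gene NLR/ID/clade/tandem labels, the
#' planted contingency table, the planted clade-pairing matrix, and the
#' planted motif placements. Identical seeds give identical output.
#'
#' @param config a [SimulationConfig()] list.
#' @param what which components to build; dropping `"tree"`/`"motifs"`
#'   speeds up replicate studies that need neither.
#' @return List with elements `annotation` ([GeneAnnotation-class]),
#'   `domains` ([DomainHitSet-class]), `tree` ([ape::phylo] or NULL),
#'   `motifs` (DataFrame or NULL), `te` (GRanges or NULL) and `truth`
#'   (list: genes, pairs, negatives, contingency, cladePairing, motifs).
#' @export
simulateDataset <- function(config,
                            what = c("annotation", "domains", "tree",
                                     "motifs")) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    nGenes <- config$nChromosomes * config$genesPerChromosome
    nNLR <- round(config$nlrFraction * nGenes)
    if (nNLR < 2L)
        stop("config error: fewer than two NLRs")
    nPairs <- round(nNLR * config$tandemRate / 2)
    negUse <- if (config$plantNegatives) 6L else 0L
    if (2L * nPairs + negUse > nNLR)
        stop("config error: tandemRate/negatives require more NLRs than ",
             "available")

    ## ---- unit plan: pairs, negatives, single NLRs, plain genes --------
    nSingle <- nNLR - 2L * nPairs - negUse
    nPlain <- nGenes - nNLR -
        (if (config$plantNegatives) 1L else 0L)  # blocker gene is extra
    if (nPlain < 0L) stop("config error: too many NLRs for gene total")
    unitType <- c(rep("pair", nPairs),
                  if (config$plantNegatives)
                      c("neg_strand", "neg_gap", "neg_between"),
                  rep("single_nlr", nSingle), rep("plain", nPlain))
    unitType <- sample(unitType)
    sizes <- c(pair = 2L, neg_strand = 2L, neg_gap = 2L,
               neg_between = 3L, single_nlr = 1L, plain = 1L)[unitType]
    uid <- rep(seq_along(unitType), sizes)
    pos <- sequence(sizes)
    type <- unitType[uid]
    n <- length(uid)
    is_nlr <- type %in% c("pair", "neg_strand", "neg_gap", "single_nlr") |
        (type == "neg_between" & pos != 2L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    strand[type %in% c("pair", "neg_gap", "neg_between") & pos == 1L] <- "-"
    strand[type %in% c("pair", "neg_gap") & pos == 2L] <- "+"
    strand[type == "neg_strand"] <- "+"
    strand[type == "neg_between" & pos == 3L] <- "+"
    gapWithin <- rep(NA_integer_, n)
    isPairGap <- type == "pair" & pos == 2L
    gapWithin[isPairGap] <- sampleRange(config$pairGapRange[1L],
                                        config$pairGapRange[2L],
                                        sum(isPairGap))
    gapWithin[type == "neg_strand" & pos == 2L] <- 1200L
    gapWithin[type == "neg_gap" & pos == 2L] <- 15001L
    gapWithin[type == "neg_between" & pos > 1L] <- 1000L

    ## ---- lay units onto chromosomes -----------------------------------
    unitChrom <- pmin(config$nChromosomes,
                      1L + (cumsum(sizes) - sizes) %/%
                          config$genesPerChromosome)
    chrom <- sprintf("chr%02d", unitChrom[uid])
    plan <- data.frame(type = type, is_nlr = is_nlr, strand = strand,
                       chrom = chrom)
    plan$length <- ifelse(
        plan$is_nlr,
        sampleRange(config$nlrGeneLengthRange[1L],
                    config$nlrGeneLengthRange[2L], n),
        sampleRange(config$geneLengthRange[1L],
                    config$geneLengthRange[2L], n))
    plan$length <- plan$length - plan$length %% 3L
    gapBefore <- sampleRange(config$intergenicGapRange[1L],
                             config$intergenicGapRange[2L], n)
    gapBefore[!is.na(gapWithin)] <- gapWithin[!is.na(gapWithin)]
    # sequential placement per chromosome: start = prev_end + gap + 1
    idxWithin <- stats::ave(seq_len(n), plan$chrom, FUN = seq_along)
    cum <- stats::ave(gapBefore + plan$length, plan$chrom, FUN = cumsum)
    plan$start <- cum - plan$length + 1L
    plan$end <- cum
    plan$gene_id <- sprintf("%sg%04d", plan$chrom, idxWithin)
    plan$protein_id <- paste0(plan$gene_id, ".p1")
    plan$aa_len <- plan$length %/% 3L - 1L

    ## ---- clades and ID status ----------------------------------------
    spec <- config$cladeSpec
    nlrIdx <- which(plan$is_nlr)
    cnt <- floor(spec$fraction * length(nlrIdx))
    while (sum(cnt) < length(nlrIdx))
        cnt[which.max(spec$fraction * length(nlrIdx) - cnt)] <-
            cnt[which.max(spec$fraction * length(nlrIdx) - cnt)] + 1L
    cladePool <- sample(rep(spec$clade, cnt))
    plan$clade <- NA_character_
    isPairUp <- plan$type == "pair" & plan$strand == "-"
    isPairDown <- plan$type == "pair" & plan$strand == "+"
    if (!is.null(config$pairClades)) {
        upLab <- config$pairClades[["upstream"]]
        dnLab <- config$pairClades[["downstream"]]
        need <- c(sum(isPairUp & plan$is_nlr), sum(isPairDown & plan$is_nlr))
        have <- c(sum(cladePool == upLab), sum(cladePool == dnLab))
        if (any(need > have))
            stop("config error: pairClades demand more tips than the ",
                 "clade spec provides")
        take <- function(lab, k) {
            i <- which(cladePool == lab)[seq_len(k)]
            cladePool <<- cladePool[-i]
            rep(lab, k)
        }
        plan$clade[which(isPairUp)] <- take(upLab, need[1L])
        plan$clade[which(isPairDown)] <- take(dnLab, need[2L])
        rest <- which(plan$is_nlr & is.na(plan$clade))
        plan$clade[rest] <- cladePool
    } else {
        plan$clade[nlrIdx] <- cladePool
    }
    plan$tandem <- plan$type == "pair"
    base <- spec$idRate[match(plan$clade, spec$clade)]
    odds <- base / (1 - base)
    odds[plan$tandem] <- odds[plan$tandem] * config$targetOddsRatio
    pID <- ifelse(base %in% c(0, 1), base, odds / (1 + odds))
    plan$has_id <- plan$is_nlr & rbinom(n, 1L, ifelse(is.na(pID), 0, pID)) == 1L

    ## ---- domain hits (vectorised) -------------------------------------
    # vector-bound uniform integer sampling
    sampleRangeV <- function(lo, hi) {
        hi <- pmax(lo, hi)
        as.integer(lo + floor(runif(length(lo)) * (hi - lo + 1L)))
    }
    pool <- config$idDomainPool
    nP <- length(pool)
    rows <- list()
    strictOf <- replicate(n, character(0), simplify = FALSE)
    relaxedOf <- replicate(n, character(0), simplify = FALSE)

    # non-NLR proteins: 0-2 housekeeping domains
    nonIdx <- which(!plan$is_nlr)
    kk <- sampleRange(0L, 2L, length(nonIdx))
    gi <- rep(nonIdx, kk)
    if (length(gi)) {
        L <- plan$aa_len[gi]
        st <- sampleRangeV(rep(1L, length(gi)), pmax(1L, L - 220L))
        rows$hk <- data.frame(
            protein_id = plan$protein_id[gi],
            domain_name = sample(c("Cytochrome_P450", "UDPGT",
                                   "Glyco_hydro_1", "PP2C", "F-box",
                                   "zf-RING_2"), length(gi),
                                 replace = TRUE),
            aa_start = st,
            aa_end = pmin(st + sampleRange(80L, 200L, length(gi)), L),
            evalue = 10^-runif(length(gi), 3, 40))
    }

    # NLR proteins: the N-terminal coiled-coil is left unannotated (as
    # domain scanners typically miss it; motifs may be planted there),
    # then NB-ARC, an LRR block, planted IDs near the C terminus, and
    # decoy hits straddling the strict/relaxed cutoffs
    nlrI <- which(plan$is_nlr)
    nN <- length(nlrI)
    L <- plan$aa_len[nlrI]
    nbStart <- sampleRange(140L, 200L, nN)
    nbEnd <- nbStart + sampleRange(250L, 300L, nN)
    plan$nb_start <- NA_integer_
    plan$nb_start[nlrI] <- nbStart
    rows$nb <- data.frame(protein_id = plan$protein_id[nlrI],
                          domain_name = "NB-ARC",
                          aa_start = nbStart, aa_end = nbEnd,
                          evalue = 10^-runif(nN, 40, 80))
    kLRR <- sampleRange(2L, 4L, nN)
    lrrStart <- nbEnd + sampleRange(20L, 60L, nN)
    lrrEnd <- pmin(L - 260L, lrrStart + 350L)
    okL <- lrrEnd > lrrStart + 60L
    gi <- rep(nlrI[okL], kLRR[okL])
    lo <- rep(lrrStart[okL], kLRR[okL])
    hi <- rep(lrrEnd[okL], kLRR[okL])
    st <- sampleRangeV(lo, hi - 60L)
    rows$lrr <- data.frame(protein_id = plan$protein_id[gi],
                           domain_name = "LRR_8",
                           aa_start = st,
                           aa_end = pmin(st + sampleRange(50L, 80L,
                                                          length(gi)), hi),
                           evalue = 10^-runif(length(gi), 0.5, 12))

    idI <- which(plan$has_id)
    plan$first_id_start <- NA_integer_
    if (length(idI)) {
        nid <- 1L + (runif(length(idI)) < 0.2)
        Li <- plan$aa_len[idI]
        pick1 <- sample.int(nP, length(idI), replace = TRUE)
        pick2 <- ((pick1 - 1L + sample.int(nP - 1L, length(idI),
                                           replace = TRUE)) %% nP) + 1L
        st1 <- sampleRangeV(Li - 230L, Li - 150L)
        en1 <- pmin(st1 + sampleRange(60L, 90L, length(idI)), Li)
        st2 <- Li - 110L
        en2 <- pmin(st2 + sampleRange(60L, 90L, length(idI)), Li)
        two <- nid == 2L
        rows$ids <- data.frame(
            protein_id = c(plan$protein_id[idI],
                           plan$protein_id[idI][two]),
            domain_name = c(pool[pick1], pool[pick2[two]]),
            aa_start = c(st1, st2[two]),
            aa_end = c(en1, en2[two]),
            evalue = 10^-runif(length(idI) + sum(two), 6, 30))
        plan$first_id_start[idI] <- st1
        for (j in seq_along(idI)) {
            nm <- if (two[j]) pool[c(pick1[j], pick2[j])] else pool[pick1[j]]
            strictOf[[idI[j]]] <- sort(nm)
            relaxedOf[[idI[j]]] <- sort(nm)
        }
    }

    # decoys: pick a family not already planted on the protein
    freePick <- function(i, avoid) {
        p <- sample.int(nP, 1L)
        while (pool[p] %in% avoid) p <- p %% nP + 1L
        pool[p]
    }
    dR <- nlrI[runif(nN) < config$decoyRelaxedRate]
    if (length(dR)) {
        dn <- vapply(dR, function(i) freePick(i, strictOf[[i]]), "")
        Ld <- plan$aa_len[dR]
        st <- sampleRangeV(Ld - 140L, Ld - 90L)
        rows$decoyR <- data.frame(protein_id = plan$protein_id[dR],
                                  domain_name = dn, aa_start = st,
                                  aa_end = st + 60L,
                                  evalue = runif(length(dR), 0.0015,
                                                 0.045))
        for (j in seq_along(dR))
            relaxedOf[[dR[j]]] <- sort(c(relaxedOf[[dR[j]]], dn[j]))
    }
    dW <- nlrI[runif(nN) < config$decoyWeakRate]
    if (length(dW)) {
        dn <- vapply(dW, function(i) freePick(i, relaxedOf[[i]]), "")
        Ld <- plan$aa_len[dW]
        st <- sampleRangeV(Ld - 85L, Ld - 65L)
        rows$decoyW <- data.frame(protein_id = plan$protein_id[dW],
                                  domain_name = dn, aa_start = st,
                                  aa_end = st + 50L,
                                  evalue = runif(length(dW), 0.06, 5))
    }
    hitTab <- do.call(rbind, rows)
    rownames(hitTab) <- NULL
    domains <- DomainHitSet(hitTab)

    ## ---- annotation object --------------------------------------------
    annotation <- GeneAnnotation(
        plan[c("gene_id", "chrom", "start", "end", "strand")],
        data.frame(protein_id = plan$protein_id, gene_id = plan$gene_id,
                   length = plan$aa_len))

    ## ---- ground truth --------------------------------------------------
    upIdx <- which(plan$type == "pair" & plan$strand == "-")
    dnIdx <- upIdx + 1L
    pairs <- data.frame(upstream_gene = plan$gene_id[upIdx],
                        downstream_gene = plan$gene_id[dnIdx],
                        chrom = plan$chrom[upIdx],
                        gap_bp = plan$start[dnIdx] - plan$end[upIdx] - 1L)
    partner <- rep(NA_character_, n)
    partner[upIdx] <- plan$gene_id[dnIdx]
    partner[dnIdx] <- plan$gene_id[upIdx]
    truthGenes <- data.frame(
        gene_id = plan$gene_id, protein_id = plan$protein_id,
        chrom = plan$chrom, start = plan$start, end = plan$end,
        strand = plan$strand, is_nlr = plan$is_nlr, clade = plan$clade,
        ids_strict = vapply(strictOf, paste, "", collapse = ","),
        ids_relaxed = vapply(relaxedOf, paste, "", collapse = ","),
        tandem = plan$tandem, tandem_partner = partner,
        unit_type = plan$type)
    withId <- plan$is_nlr & vapply(strictOf, length, 1L) > 0L
    contingency <- matrix(
        c(sum(withId & plan$tandem), sum(withId & !plan$tandem),
          sum(plan$is_nlr & !withId & plan$tandem),
          sum(plan$is_nlr & !withId & !plan$tandem)),
        nrow = 2L, byrow = TRUE,
        dimnames = list(group = c("group", "other"),
                        status = c("tandem", "single")))
    cladeLevels <- spec$clade
    cladePairing <- matrix(0L, length(cladeLevels), length(cladeLevels),
                           dimnames = list(upstream = cladeLevels,
                                           downstream = cladeLevels))
    if (nrow(pairs)) {
        tb <- table(factor(plan$clade[upIdx], cladeLevels),
                    factor(plan$clade[dnIdx], cladeLevels))
        cladePairing[] <- as.integer(tb)
    }

    ## ---- tree ----------------------------------------------------------
    tree <- NULL
    if ("tree" %in% what) {
        tips <- split(plan$protein_id[nlrIdx], plan$clade[nlrIdx])
        tips <- tips[intersect(spec$clade, names(tips))]
        tree <- simulateTree(tips)
    }

    ## ---- motifs --------------------------------------------------------
    motifs <- NULL
    truthMotifs <- NULL
    if ("motifs" %in% what && length(config$motifSpec)) {
        mrows <- list()
        for (ms in config$motifSpec) {
            cand <- which(plan$is_nlr & plan$clade == ms$clade)
            takeN <- rbinom(length(cand), 1L, ms$rate) == 1L
            for (i in cand[takeN]) {
                L <- plan$aa_len[i]
                if (!is.null(ms$gapRange) && plan$has_id[i]) {
                    gap <- sampleRange(ms$gapRange[1L], ms$gapRange[2L], 1L)
                    mEnd <- plan$first_id_start[i] - 1L - gap
                    mStart <- mEnd - ms$length + 1L
                } else if (!is.null(ms$gapRange)) {
                    mEnd <- L - sampleRange(250L, 290L, 1L)
                    mStart <- mEnd - ms$length + 1L
                    gap <- NA_integer_
                } else {
                    mEnd <- plan$nb_start[i] - sampleRange(5L, 15L, 1L)
                    mStart <- mEnd - ms$length + 1L
                    gap <- NA_integer_
                }
                if (mStart < 1L) next
                mrows[[length(mrows) + 1L]] <- data.frame(
                    protein_id = plan$protein_id[i], motif_id = ms$motif,
                    aa_start = mStart, aa_end = mEnd,
                    score = round(runif(1, 15, 60), 2),
                    planted_gap = gap)
            }
        }
        truthMotifs <- if (length(mrows)) do.call(rbind, mrows) else
            data.frame(protein_id = character(), motif_id = character(),
                       aa_start = integer(), aa_end = integer(),
                       score = numeric(), planted_gap = integer())
        motifs <- DataFrame(truthMotifs[c("protein_id", "motif_id",
                                          "aa_start", "aa_end", "score")])
    }

    ## ---- TE intervals --------------------------------------------------
    te <- NULL
    teTruth <- NULL
    if (!is.null(config$teOverlap)) {
        cl <- config$teOverlap$clade
        rate <- config$teOverlap$rate
        inCl <- which(plan$is_nlr & plan$clade == cl)
        hitGenes <- inCl[rbinom(length(inCl), 1L, rate) == 1L]
        # TE inserted inside the gene body: overlaps exactly this gene
        teRows <- data.frame(chrom = plan$chrom[hitGenes],
                             start = plan$start[hitGenes] + 10L,
                             end = plan$start[hitGenes] + 510L)
        # background TEs strictly inside the wide plain-gene gaps
        bg <- which(plan$type == "plain" &
                    plan$start > 12000L)
        bg <- bg[seq_len(min(20L, length(bg)))]
        if (length(bg))
            teRows <- rbind(teRows, data.frame(
                chrom = plan$chrom[bg],
                start = plan$start[bg] - 9000L,
                end = plan$start[bg] - 6000L))
        te <- GRanges(teRows$chrom, IRanges(teRows$start, teRows$end))
        teTruth <- list(clade = cl, rate = rate,
                        overlapping_genes = plan$gene_id[hitGenes],
                        n_clade_genes = length(inCl))
    }

    list(annotation = annotation, domains = domains, tree = tree,
         motifs = motifs, te = te,
         truth = list(genes = truthGenes, pairs = pairs,
                      contingency = contingency,
                      cladePairing = cladePairing,
                      motifs = truthMotifs, te = teTruth,
                      config = config))
}

#' Simulate a clade-structured support tree
#'
#' Builds a tree whose planted clades are monophyletic subtrees hanging
#' off a weakly supported backbone: clade stems carry high bootstrap
#' supports and are long enough that every clade's mean root-to-tip depth
#' exceeds the founding threshold, while backbone and within-clade nodes
#' are weakly supported — the signature of recent within-clade radiations
#' and a poorly resolved deep backbone, under which [partitionClades()]
#' recovers the planted structure exactly.
#'
#' @param tips named list: clade label -> character vector of tip ids
#'   (>= 2 clades or >= 2 tips overall).
#' @param seed optional integer seed (omit to use the current RNG state,
#'   e.g. inside [simulateDataset()]).
#' @param stemLength stem branch length of each clade.
#' @param withinEdgeRange branch-length range inside clades.
#' @param backboneEdgeRange branch-length range along the backbone.
#' @param stemSupportRange,withinSupportRange,backboneSupportRange
#'   bootstrap ranges for stem, within-clade and backbone nodes.
#' @return An [ape::phylo] tree with supports as node labels and an
#'   attribute `"plantedClades"` (the `tips` list).
#' @export
simulateTree <- function(tips, seed = NULL, stemLength = 2.0,
                         withinEdgeRange = c(0.02, 0.12),
                         backboneEdgeRange = c(0.05, 0.15),
                         stemSupportRange = c(95L, 100L),
                         withinSupportRange = c(40L, 75L),
                         backboneSupportRange = c(30L, 60L)) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(is.list(tips), length(tips) >= 1L)
    if (sum(lengths(tips)) < 2L)
        stop("config error: need at least two tips")
    token <- function(ids, stemSup) {
        if (length(ids) == 1L)
            return(paste0(ids, ":", format(stemLength + 0.2)))
        t <- ape::rtree(length(ids), tip.label = sample(ids))
        t$edge.length <- runif(nrow(t$edge), withinEdgeRange[1L],
                               withinEdgeRange[2L])
        t$node.label <- c(stemSup,
                          sampleRange(withinSupportRange[1L],
                                      withinSupportRange[2L],
                                      t$Nnode - 1L))
        sub(";$", paste0(":", format(stemLength)), ape::write.tree(t))
    }
    stemSup <- sampleRange(stemSupportRange[1L], stemSupportRange[2L],
                           length(tips))
    toks <- mapply(token, tips, stemSup)
    k <- length(toks)
    # assemble with an unrooted-style (trifurcating) root so that every
    # unrooted edge carries exactly one support label, as tree builders
    # emit; for two clades the single central edge keeps one label
    if (k == 1L) {
        newick <- paste0(sub(paste0(":", format(stemLength), "$"), "",
                             toks[1L]), ";")
    } else if (k == 2L) {
        tok2 <- sub(")[0-9]+:", "):", toks[2L])  # drop duplicate label
        newick <- paste0("(", toks[1L], ",", tok2, ");")
    } else {
        acc <- toks[1L]
        if (k > 3L)
            for (i in 2L:(k - 2L)) {
                bb <- sampleRange(backboneSupportRange[1L],
                                  backboneSupportRange[2L], 1L)
                bl <- format(runif(1, backboneEdgeRange[1L],
                                   backboneEdgeRange[2L]))
                acc <- paste0("(", acc, ",", toks[i], ")", bb, ":", bl)
            }
        newick <- paste0("(", acc, ",", toks[k - 1L], ",", toks[k], ");")
    }
    tree <- ape::read.tree(text = newick)
    attr(tree, "plantedClades") <- tips
    tree
}

#' Write a simulated dataset to disk
#'
#' Emits annotation.gff3, domains.tsv, tree.nwk, motifs.tsv, te.bed (when
#' planted) and truth.json into a directory; files parse back through the
#' package readers. Identical seeds give byte-identical files.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(annotation = file.path(dir, "annotation.gff3"),
               domains = file.path(dir, "domains.tsv"))
    writeGeneAnnotation(sim$annotation, files[["annotation"]])
    h <- as.data.frame(domainHits(sim$domains))
    con <- file(files[["domains"]], "wt")
    writeLines("# protein_id\tdomain_name\taa_start\taa_end\tevalue", con)
    suppressWarnings(write.table(h, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    if (!is.null(sim$tree)) {
        files[["tree"]] <- file.path(dir, "tree.nwk")
        writeSupportTree(sim$tree, files[["tree"]])
    }
    if (!is.null(sim$motifs)) {
        files[["motifs"]] <- file.path(dir, "motifs.tsv")
        write.table(as.data.frame(sim$motifs), files[["motifs"]],
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(sim$te)) {
        files[["te"]] <- file.path(dir, "te.bed")
        writeLines(sprintf("%s\t%d\t%d",
                           as.character(seqnames(sim$te)),
                           start(sim$te) - 1L, end(sim$te)),
                   files[["te"]])
    }
    files[["truth"]] <- file.path(dir, "truth.json")
    truth <- sim$truth
    truth$config <- unclass(truth$config)
    truth$contingency <- as.data.frame(truth$contingency)
    truth$cladePairing <- as.data.frame(truth$cladePairing)
    jsonlite::write_json(truth, files[["truth"]], dataframe = "columns",
                         na = "null", digits = NA, auto_unbox = TRUE)
    invisible(files)
}
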