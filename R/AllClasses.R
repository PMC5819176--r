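#' Analysis thresholds
#'
#' Container for every numeric cutoff used across the pipeline. Defaults
#' follow the published analysis: integrated domains are called at
#' e-value < 0.001 (strict) with a lower-stringency set at e-value < 0.05
#' (relaxed); structural domains (LRR/AAA/TIR/RPW8) are displayed up to
#' e-value 10; proteins need >= 70% coverage of the NB-ARC1-ARC2 alignment;
#' head-to-head pairs may be at most 15 kbp apart; unannotated regions kept
#' for motif discovery are >= 20 aa; clades are founded at bootstrap
#' support >= 80 and mean root-to-tip depth > 1.4 substitutions/site; the
#' conserved integration-site motif (CID) counts as "immediately upstream"
#' of an ID within a 50 aa window.
#'
#' @slot idEvalueStrict numeric, strict ID e-value cutoff (exclusive).
#' @slot idEvalueRelaxed numeric, relaxed ID e-value cutoff (exclusive).
#' @slot structuralEvalue numeric, display cutoff for structural domains.
#' @slot nbarcCoverageMin numeric fraction, minimum NB-ARC model coverage.
#' @slot tandemMaxGap integer bp, maximum intergenic gap of a tandem pair
#'   (inclusive).
#' @slot minRegionLen integer aa, minimum unannotated-region length.
#' @slot brlMin numeric, minimum mean root-to-tip depth for clade founding.
#' @slot supportMin integer percent, minimum bootstrap support for clade
#'   founding (inclusive).
#' @slot cidWindow integer aa, maximum CID-to-ID gap still called
#'   "immediately upstream".
#' @export
setClass("NLRThresholds", representation(
    idEvalueStrict   = "numeric",
    idEvalueRelaxed  = "numeric",
    structuralEvalue = "numeric",
    nbarcCoverageMin = "numeric",
    tandemMaxGap     = "integer",
    minRegionLen     = "integer",
    brlMin           = "numeric",
    supportMin       = "integer",
    cidWindow        = "integer"))

setValidity("NLRThresholds", function(object) {
    msg <- character()
    vals <- c(object@idEvalueStrict, object@idEvalueRelaxed,
              object@structuralEvalue, object@nbarcCoverageMin,
              object@tandemMaxGap, object@minRegionLen, object@brlMin,
              object@supportMin, object@cidWindow)
    if (any(!is.finite(vals)) || any(vals <= 0))
        msg <- c(msg, "all thresholds must be finite and strictly positive")
    if (object@idEvalueStrict > object@idEvalueRelaxed)
        msg <- c(msg, "idEvalueStrict must be <= idEvalueRelaxed")
    if (length(msg)) msg else TRUE
})

#' Construct an NLRThresholds object
#'
#' @param idEvalueStrict strict ID e-value cutoff (default 1e-3).
#' @param idEvalueRelaxed relaxed ID e-value cutoff (default 0.05).
#' @param structuralEvalue structural-domain display cutoff (default 10).
#' @param nbarcCoverageMin minimum NB-ARC alignment coverage (default 0.70).
#' @param tandemMaxGap maximum tandem intergenic gap in bp (default 15000).
#' @param minRegionLen minimum unannotated region length in aa (default 20).
#' @param brlMin minimum mean root-to-tip depth in substitutions/site
#'   (default 1.4).
#' @param supportMin minimum bootstrap support percent (default 80).
#' @param cidWindow CID-to-ID window in aa (default 50).
#' @return An [NLRThresholds-class] object.
#' @examples
#' NLRThresholds()
#' NLRThresholds(tandemMaxGap = 10000L)
#' @export
NLRThresholds <- function(idEvalueStrict = 1e-3, idEvalueRelaxed = 0.05,
                          structuralEvalue = 10, nbarcCoverageMin = 0.70,
                          tandemMaxGap = 15000L, minRegionLen = 20L,
                          brlMin = 1.4, supportMin = 80L, cidWindow = 50L) {
    new("NLRThresholds",
        idEvalueStrict = as.numeric(idEvalueStrict),
        idEvalueRelaxed = as.numeric(idEvalueRelaxed),
        structuralEvalue = as.numeric(structuralEvalue),
        nbarcCoverageMin = as.numeric(nbarcCoverageMin),
        tandemMaxGap = as.integer(tandemMaxGap),
        minRegionLen = as.integer(minRegionLen),
        brlMin = as.numeric(brlMin),
        supportMin = as.integer(supportMin),
        cidWindow = as.integer(cidWindow))
}

setMethod("show", "NLRThresholds", function(object) {
    cat("NLRThresholds\n")
    v <- thresholdValues(object)
    for (nm in names(v)) cat(sprintf("  %-17s %s\n", nm, format(v[[nm]])))
})

#' Thresholds as a named list
#' @param object an [NLRThresholds-class] object.
#' @return Named list of threshold values.
#' @export
thresholdValues <- function(object) {
    stopifnot(is(object, "NLRThresholds"))
    nms <- slotNames(object)
    setNames(lapply(nms, slot, object = object), nms)
}

#' Structural-domain exclusion rules
#'
#' An integrated domain is any Pfam domain on an NLR other than the
#' structural set: NB-ARC itself, LRR, AAA, TIR and RPW8. NB-ARC, TIR and
#' RPW8 are matched exactly; LRR and AAA are matched as substrings because
#' Pfam splits them into many families (LRR_1, LRR_8, AAA_22, ...).
#'
#' @slot exact character, family names excluded by exact match.
#' @slot substring character, patterns excluded wherever they occur in a
#'   family name.
#' @export
setClass("DomainExclusion", representation(
    exact = "character", substring = "character"))

setValidity("DomainExclusion", function(object) {
    if (length(object@exact) + length(object@substring) == 0L)
        return("exclusion set must be non-empty")
    if (!"NB-ARC" %in% object@exact)
        return("NB-ARC must always be excluded")
    TRUE
})

#' Construct a DomainExclusion object
#' @param exact family names excluded by exact match.
#' @param substring patterns excluded by substring match.
#' @return A [DomainExclusion-class] object.
#' @examples
#' DomainExclusion()
#' @export
DomainExclusion <- function(exact = c("NB-ARC", "PF00931", "TIR", "RPW8"),
                            substring = c("LRR", "AAA")) {
    new("DomainExclusion", exact = as.character(exact),
        substring = as.character(substring))
}

setMethod("show", "DomainExclusion", function(object) {
    cat("DomainExclusion\n  exact:    ",
        paste(object@exact, collapse = ", "),
        "\n  substring:", paste(object@substring, collapse = ", "), "\n")
})

#' Gene annotation with protein isoforms
#'
#' A located, stranded gene set plus its protein isoforms. Genes are held
#' as a [GenomicRanges::GRanges] (names = gene ids, strand strictly + or -)
#' and isoforms as a DataFrame with columns `protein_id`, `gene_id` and
#' `length` (aa). Protein-coding genes must have at least one isoform with
#' a known length; genes lacking one are dropped on read with a warning.
#'
#' @slot genes GRanges of genes; names are unique gene ids.
#' @slot isoforms DataFrame with protein_id, gene_id, length (aa).
#' @export
setClass("GeneAnnotation", representation(
    genes = "GRanges", isoforms = "DataFrame"))

setValidity("GeneAnnotation", function(object) {
    msg <- character()
    gid <- names(object@genes)
    if (is.null(gid) || anyDuplicated(gid))
        msg <- c(msg, "gene ids must be present and unique")
    if (length(object@genes) && !all(as.character(strand(object@genes)) %in% c("+", "-")))
        msg <- c(msg, "every gene must be on strand + or -")
    iso <- object@isoforms
    need <- c("protein_id", "gene_id", "length")
    if (!all(need %in% colnames(iso)))
        msg <- c(msg, "isoforms need columns protein_id, gene_id, length")
    else {
        if (anyDuplicated(iso$protein_id))
            msg <- c(msg, "protein ids must be unique")
        if (length(iso$gene_id) && !all(iso$gene_id %in% gid))
            msg <- c(msg, "isoform gene_id not in gene set")
        if (length(iso$length) && any(!is.finite(iso$length) | iso$length <= 0))
            msg <- c(msg, "isoform lengths must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneAnnotation from plain tables
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand.
#' @param isoforms data.frame with columns protein_id, gene_id, length.
#' @return A [GeneAnnotation-class] object with genes sorted by
#'   (chrom, start).
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 900,
#'                 strand = "+")
#' p <- data.frame(protein_id = "g1.p1", gene_id = "g1", length = 200)
#' GeneAnnotation(g, p)
#' @export
GeneAnnotation <- function(genes, isoforms) {
    if (any(genes$end < genes$start))
        stop("validation error: gene with end < start: ",
             paste(genes$gene_id[genes$end < genes$start], collapse = ", "))
    gr <- GRanges(seqnames = as.character(genes$chrom),
                  ranges = IRanges(as.integer(genes$start),
                                   as.integer(genes$end)),
                  strand = as.character(genes$strand))
    names(gr) <- as.character(genes$gene_id)
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    iso <- DataFrame(protein_id = as.character(isoforms$protein_id),
                     gene_id = as.character(isoforms$gene_id),
                     length = as.integer(isoforms$length))
    new("GeneAnnotation", genes = gr, isoforms = iso)
}

setMethod("show", "GeneAnnotation", function(object) {
    cat(sprintf("GeneAnnotation: %d genes on %d sequences, %d isoforms\n",
                length(object@genes),
                length(unique(as.character(seqnames(object@genes)))),
                nrow(object@isoforms)))
})

#' @describeIn GeneAnnotation-class the gene GRanges.
#' @param x a GeneAnnotation.
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @rdname GeneAnnotation-class
#' @param ... unused.
#' @export
setMethod("genes", "GeneAnnotation", function(x, ...) x@genes)

#' @describeIn GeneAnnotation-class the isoform DataFrame.
#' @export
setGeneric("isoforms", function(x) standardGeneric("isoforms"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("isoforms", "GeneAnnotation", function(x) x@isoforms)

#' Scored domain intervals on proteins
#'
#' One row per domain hit: `protein_id`, `domain_name` (Pfam family name or
#' accession), `aa_start`, `aa_end` (1-based closed, amino acids) and
#' `evalue`. Positional invariants (aa_start <= aa_end, evalue >= 0) are
#' enforced; the aa_end <= protein-length invariant is checked wherever a
#' protein length is available.
#'
#' @slot hits DataFrame of validated hits.
#' @export
setClass("DomainHitSet", representation(hits = "DataFrame"))

setValidity("DomainHitSet", function(object) {
    h <- object@hits
    need <- c("protein_id", "domain_name", "aa_start", "aa_end", "evalue")
    if (!all(need %in% colnames(h)))
        return(paste("hits need columns", paste(need, collapse = ", ")))
    bad <- which(h$aa_start > h$aa_end | h$aa_start < 1L)
    if (length(bad))
        return(paste("inverted or non-positive aa interval at rows",
                     paste(head(bad, 5L), collapse = ", ")))
    bad <- which(h$evalue < 0)
    if (length(bad))
        return(paste("negative e-value at rows",
                     paste(head(bad, 5L), collapse = ", ")))
    TRUE
})

#' Construct a DomainHitSet from a plain table
#' @param hits data.frame with columns protein_id, domain_name, aa_start,
#'   aa_end, evalue.
#' @return A [DomainHitSet-class] object, rows ordered by
#'   (protein_id, aa_start).
#' @examples
#' DomainHitSet(data.frame(protein_id = "p1", domain_name = "NB-ARC",
#'                         aa_start = 160, aa_end = 450, evalue = 1e-50))
#' @export
DomainHitSet <- function(hits) {
    h <- DataFrame(protein_id = as.character(hits$protein_id),
                   domain_name = as.character(hits$domain_name),
                   aa_start = as.integer(hits$aa_start),
                   aa_end = as.integer(hits$aa_end),
                   evalue = as.numeric(hits$evalue))
    h <- h[order(h$protein_id, h$aa_start), , drop = FALSE]
    rownames(h) <- NULL
    new("DomainHitSet", hits = h)
}

setMethod("show", "DomainHitSet", function(object) {
    cat(sprintf("DomainHitSet: %d hits on %d proteins, %d families\n",
                nrow(object@hits), length(unique(object@hits$protein_id)),
                length(unique(object@hits$domain_name))))
})

#' @describeIn DomainHitSet-class the hit DataFrame.
#' @param x a DomainHitSet.
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))

#' @rdname DomainHitSet-class
#' @export
setMethod("domainHits", "DomainHitSet", function(x) x@hits)

#' Clade partition of a support tree
#'
#' Assignment of every tip to exactly one clade label, obtained from the
#' support/branch-length founding rule (see [partitionClades()]) possibly
#' with manual overrides.
#'
#' @slot cladeOf named character, tip id -> clade label.
#' @slot ruleParams list with brlMin and supportMin actually applied.
#' @slot foundingNodes named integer, clade label -> founding node number
#'   (absent for the residual clade).
#' @export
setClass("CladePartition", representation(
    cladeOf = "character", ruleParams = "list", foundingNodes = "integer"))

setValidity("CladePartition", function(object) {
    if (is.null(names(object@cladeOf)) || anyDuplicated(names(object@cladeOf)))
        return("cladeOf must be a named vector with unique tip ids")
    if (any(is.na(object@cladeOf)))
        return("every tip must carry a clade label")
    TRUE
})

setMethod("show", "CladePartition", function(object) {
    tab <- table(object@cladeOf)
    cat(sprintf("CladePartition: %d tips in %d clades\n",
                length(object@cladeOf), length(tab)))
    print(tab)
})

#' @describeIn CladePartition-class named vector tip id -> clade label.
#' @param x a CladePartition.
#' @export
setGeneric("cladeOf", function(x) standardGeneric("cladeOf"))

#' @rdname CladePartition-class
#' @export
setMethod("cladeOf", "CladePartition", function(x) x@cladeOf)

#' A 2x2 contingency table with its exact-test result
#'
#' Rows are group membership (e.g. carries an integrated domain, or member
#' of the designated clade), columns are tandem vs single status. The
#' p-value is the conventional two-sided Fisher exact probability; the odds
#' ratio is the sample (cross-product) estimate, possibly infinite.
#'
#' @slot counts 2x2 integer matrix (a, b / c, d).
#' @slot pValue two-sided exact p-value in (0, 1], NA until tested.
#' @slot oddsRatio sample odds ratio a*d/(b*c).
#' @export
setClass("ContingencyResult", representation(
    counts = "matrix", pValue = "numeric", oddsRatio = "numeric"))

setValidity("ContingencyResult", function(object) {
    ct <- object@counts
    if (!all(dim(ct) == c(2L, 2L)))
        return("counts must be a 2x2 matrix")
    if (any(ct < 0) || any(ct != round(ct)))
        return("counts must be non-negative integers")
    TRUE
})

#' Construct a ContingencyResult
#' @param a,b,c,d cell counts: a = group & tandem, b = group & single,
#'   c = other & tandem, d = other & single.
#' @param test if TRUE (default) run [fisherExact2x2()] immediately.
#' @return A [ContingencyResult-class] object.
#' @examples
#' ContingencyResult(50, 365, 268, 5511)
#' @export
ContingencyResult <- function(a, b, c, d, test = TRUE) {
    ct <- matrix(as.integer(c(a, b, c, d)), nrow = 2L, byrow = TRUE,
                 dimnames = list(group = c("group", "other"),
                                 status = c("tandem", "single")))
    obj <- new("ContingencyResult", counts = ct, pValue = NA_real_,
               oddsRatio = NA_real_)
    if (test) obj <- fisherExact2x2(obj) else obj
}

setMethod("show", "ContingencyResult", function(object) {
    cat("ContingencyResult\n")
    print(object@counts)
    cat(sprintf("  two-sided Fisher p = %s, odds ratio = %s\n",
                format(object@pValue, digits = 3),
                format(object@oddsRatio, digits = 3)))
})

#' @describeIn ContingencyResult-class the 2x2 count matrix.
#' @param object a ContingencyResult.
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname ContingencyResult-class
#' @param ... unused.
#' @export
setMethod("counts", "ContingencyResult", function(object, ...) object@counts)

#' @describeIn ContingencyResult-class the two-sided exact p-value.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname ContingencyResult-class
#' @export
setMethod("pValue", "ContingencyResult", function(object) object@pValue)

#' @describeIn ContingencyResult-class the sample odds ratio.
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' @rdname ContingencyResult-class
#' @export
setMethod("oddsRatio", "ContingencyResult", function(object) object@oddsRatio)
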