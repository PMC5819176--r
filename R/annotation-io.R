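#' Read a gene annotation into a GeneAnnotation object
#'
#' Parses GFF3 (gene/mRNA/CDS features) or a documented tabular fallback
#' into the shared data model. Isoform (protein) lengths are taken, in
#' order of preference, from a `protein_length` attribute on the mRNA line,
#' from the summed CDS length (aa = CDS bp / 3 - 1, the CDS including the
#' stop codon), or from an optional protein FASTA. Genes with no isoform
#' of known length are excluded with a warning.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"table"`. The tabular dialect is
#'   tab-separated with header columns gene_id, chrom, start, end, strand,
#'   protein_id, protein_length (one row per isoform).
#' @param proteinFasta optional protein FASTA supplying isoform lengths;
#'   sequence names must be protein ids.
#' @return A [GeneAnnotation-class] object (genes sorted by chrom, start).
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tx\tgene\t100\t900\t.\t+\t.\tID=g1",
#'   "chr1\tx\tmRNA\t100\t900\t.\t+\t.\tID=g1.p1;Parent=g1;protein_length=200"),
#'   gff)
#' readGeneAnnotation(gff)
#' @export
readGeneAnnotation <- function(path, dialect = c("gff3", "table"),
                               proteinFasta = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stopValidation("annotation file not found: ", path)
    if (dialect == "table") {
        tab <- read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
        need <- c("gene_id", "chrom", "start", "end", "strand",
                  "protein_id", "protein_length")
        if (!all(need %in% colnames(tab)))
            stopValidation("tabular annotation needs columns ",
                           paste(need, collapse = ", "))
        genes <- unique(tab[c("gene_id", "chrom", "start", "end", "strand")])
        iso <- data.frame(protein_id = tab$protein_id,
                          gene_id = tab$gene_id,
                          length = tab$protein_length)
        return(GeneAnnotation(genes, iso))
    }
    .gffPrescan(path)
    gr <- rtracklayer::import(path, format = "gff3")
    typ <- as.character(gr$type)
    gn <- gr[typ == "gene"]
    mr <- gr[typ == "mRNA"]
    cds <- gr[typ == "CDS"]
    if (!length(gn)) stopValidation("no gene features in ", path)
    gid <- as.character(gn$ID)
    badStrand <- !as.character(strand(gn)) %in% c("+", "-")
    if (any(badStrand))
        stopValidation("validation error: gene(s) without +/- strand: ",
                       paste(gid[badStrand], collapse = ", "))
    mparent <- vapply(as.list(mr$Parent), function(p)
        if (length(p)) p[[1L]] else NA_character_, "")
    if (any(is.na(mparent)) || !all(mparent %in% gid))
        stopValidation("validation error: mRNA without a parent gene: ",
                       paste(as.character(mr$ID)[is.na(mparent) |
                                                 !mparent %in% gid],
                             collapse = ", "))
    mid <- as.character(mr$ID)
    # isoform lengths: protein_length attribute, then CDS, then FASTA
    len <- rep(NA_real_, length(mr))
    if ("protein_length" %in% colnames(mcols(mr)))
        len <- suppressWarnings(as.numeric(as.character(mr$protein_length)))
    if (length(cds) && anyNA(len)) {
        cparent <- vapply(as.list(cds$Parent), function(p)
            if (length(p)) p[[1L]] else NA_character_, "")
        bp <- tapply(width(cds), factor(cparent, levels = mid), sum)
        cdsLen <- floor(as.numeric(bp) / 3) - 1L
        len[is.na(len)] <- cdsLen[is.na(len)]
    }
    if (!is.null(proteinFasta) && anyNA(len)) {
        aa <- readProteinLengths(proteinFasta)
        len[is.na(len)] <- aa[mid[is.na(len)]]
    }
    keep <- !is.na(len) & len > 0
    if (any(!keep))
        warning("excluding ", sum(!keep),
                " isoform(s) with unknown protein length")
    iso <- data.frame(protein_id = mid[keep], gene_id = mparent[keep],
                      length = len[keep])
    hasIso <- gid %in% iso$gene_id
    if (any(!hasIso))
        warning("excluding ", sum(!hasIso),
                " gene(s) with no isoform of known length: ",
                paste(head(gid[!hasIso], 5L), collapse = ", "))
    genes <- data.frame(gene_id = gid[hasIso],
                        chrom = as.character(seqnames(gn))[hasIso],
                        start = start(gn)[hasIso], end = end(gn)[hasIso],
                        strand = as.character(strand(gn))[hasIso])
    GeneAnnotation(genes, iso)
}

# line-level structural checks so malformed GFF3 fails with a line number
.gffPrescan <- function(path) {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln) || startsWith(ln, "#")) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(f) != 9L)
            stop("parse error at line ", i, ": expected 9 tab-separated ",
                 "fields, found ", length(f))
        s <- suppressWarnings(as.numeric(f[4L]))
        e <- suppressWarnings(as.numeric(f[5L]))
        if (is.na(s) || is.na(e))
            stop("parse error at line ", i, ": non-numeric coordinates")
        if (e < s)
            stop("parse error at line ", i, ": end < start")
    }
    invisible(TRUE)
}

#' Write a GeneAnnotation as GFF3
#'
#' Emits gene, mRNA and CDS features. Isoform lengths are carried on the
#' mRNA line as a `protein_length` attribute so that write-then-read is
#' the identity on the data model. Coordinates are 1-based closed.
#'
#' @param annotation a [GeneAnnotation-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
    gr <- genes(annotation)
    iso <- isoforms(annotation)
    chrom <- as.character(seqnames(gr))
    st <- start(gr); en <- end(gr); sd <- as.character(strand(gr))
    gid <- names(gr)
    geneLines <- sprintf("%s\tNLRIDscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         chrom, st, en, sd, gid)
    idx <- match(iso$gene_id, gid)
    mrnaLines <- sprintf(
        "%s\tNLRIDscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;protein_length=%d",
        chrom[idx], st[idx], en[idx], sd[idx],
        iso$protein_id, iso$gene_id, iso$length)
    cdsLines <- sprintf(
        "%s\tNLRIDscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
        chrom[idx], st[idx], en[idx], sd[idx],
        iso$protein_id, iso$protein_id)
    ord <- order(chrom[idx], st[idx])
    writeLines(c("##gff-version 3",
                 "# coordinates: 1-based, closed intervals",
                 geneLines[order(chrom, st)],
                 mrnaLines[ord], cdsLines[ord]), path)
    invisible(path)
}

#' Read a domain-hit table
#'
#' Tab-separated table in the layout produced by standard Pfam scanning:
#' header columns `protein_id`, `domain_name`, `aa_start`, `aa_end`,
#' `evalue`; '#' comment lines allowed. Rows violating the interval or
#' e-value invariants abort with the offending row numbers.
#'
#' @param path input file.
#' @return A [DomainHitSet-class] object (empty table gives an empty set).
#' @export
readDomainHits <- function(path) {
    if (!file.exists(path))
        stopValidation("domain-hit file not found: ", path)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("protein_id", "domain_name", "aa_start", "aa_end", "evalue")
    if (nrow(tab) == 0L)
        return(DomainHitSet(data.frame(protein_id = character(),
                                       domain_name = character(),
                                       aa_start = integer(),
                                       aa_end = integer(),
                                       evalue = numeric())))
    if (!all(need %in% colnames(tab)))
        stopValidation("domain-hit table needs columns ",
                       paste(need, collapse = ", "))
    bad <- which(tab$aa_start > tab$aa_end | tab$evalue < 0 |
                 tab$aa_start < 1)
    if (length(bad))
        stopValidation("validation error in domain-hit rows: ",
                       paste(bad, collapse = ", "))
    DomainHitSet(tab[need])
}

#' Write a domain-hit table
#' @param hitset a [DomainHitSet-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDomainHits <- function(hitset, path) {
    writeResultTable(as.data.frame(domainHits(hitset)), path)
}

#' Read a Newick tree with bootstrap supports
#'
#' Internal-node labels, where present, must parse as integers in
#' [0, 100]; they are interpreted as bootstrap support percentages.
#' Missing labels are recorded as unknown (NA), never as zero.
#'
#' @param path Newick file (or a string via `text`).
#' @param text optional Newick string instead of a file.
#' @return An [ape::phylo] tree.
#' @examples
#' readSupportTree(text = "((A:0.1,B:0.2)95:0.3,C:0.4);")
#' @export
readSupportTree <- function(path = NULL, text = NULL) {
    tr <- tryCatch(
        if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
        error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
        stop("parse error: not a valid Newick tree")
    if (anyDuplicated(tr$tip.label))
        stopValidation("validation error: duplicate tip id(s): ",
                       paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                             collapse = ", "))
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
        stopValidation("validation error: negative branch length")
    sup <- nodeSupports(tr, check = TRUE)
    stopifnot(all(is.na(sup) | (sup >= 0 & sup <= 100)))
    tr
}

#' Bootstrap supports of the internal nodes
#'
#' @param tree an [ape::phylo] tree.
#' @param check if TRUE, non-numeric non-empty labels are an error.
#' @return Integer vector, one entry per internal node (NA where absent).
#' @export
nodeSupports <- function(tree, check = FALSE) {
    lab <- tree$node.label
    if (is.null(lab)) return(rep(NA_integer_, tree$Nnode))
    sup <- suppressWarnings(as.numeric(lab))
    bad <- nzchar(lab) & !is.na(lab) & is.na(sup)
    if (check && any(bad))
        stopValidation("validation error: internal-node label(s) not a ",
                       "support percentage: ",
                       paste(unique(lab[bad]), collapse = ", "))
    bad2 <- !is.na(sup) & (sup < 0 | sup > 100)
    if (check && any(bad2))
        stopValidation("validation error: support outside [0, 100]")
    as.integer(round(sup))
}

#' Write a tree in Newick format
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSupportTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Read BED intervals (e.g. transposable-element coordinates)
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based closed convention on read (rtracklayer does the conversion).
#'
#' @param path BED file (>= 3 columns).
#' @return A [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path) {
    if (!file.exists(path))
        stopValidation("BED file not found: ", path)
    rtracklayer::import(path, format = "bed")
}

#' Protein lengths from a FASTA file
#' @param path protein FASTA.
#' @return Named numeric vector of lengths (aa), names are protein ids.
#' @export
readProteinLengths <- function(path) {
    aa <- readAAStringSet(path)
    nm <- sub("\\s.*$", "", names(aa))
    setNames(as.numeric(width(aa)), nm)
}

#' Read a motif-hit table
#'
#' Tab-separated, header columns `protein_id`, `motif_id`, `aa_start`,
#' `aa_end`, `score` — compatible with tabular output of standard motif
#' scanners.
#'
#' @param path input file.
#' @return DataFrame of validated motif hits.
#' @export
readMotifHits <- function(path) {
    if (!file.exists(path))
        stopValidation("motif-hit file not found: ", path)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("protein_id", "motif_id", "aa_start", "aa_end", "score")
    if (nrow(tab) == 0L)
        return(DataFrame(protein_id = character(), motif_id = character(),
                         aa_start = integer(), aa_end = integer(),
                         score = numeric()))
    if (!all(need %in% colnames(tab)))
        stopValidation("motif-hit table needs columns ",
                       paste(need, collapse = ", "))
    if (any(tab$aa_start > tab$aa_end | tab$aa_start < 1))
        stopValidation("validation error: inverted motif interval")
    DataFrame(tab[need])
}
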