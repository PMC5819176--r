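#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path, the
#' rooting used for all NB-ARC trees here. Bootstrap labels are carried
#' through re-rooting as node supports. A tree whose branch lengths are
#' all zero cannot define a midpoint; it is returned unchanged with a
#' warning.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return A rooted [ape::phylo] tree; tip-to-tip path lengths unchanged.
#' @examples
#' midpointRoot(readSupportTree(text = "(A:1,(B:1,C:4):1);"))
#' @export
midpointRoot <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    if (Ntip(tree) < 2L)
        stopValidation("midpoint rooting needs at least 2 tips")
    if (is.null(tree$edge.length))
        stopValidation("midpoint rooting needs branch lengths")
    if (all(tree$edge.length == 0)) {
        warning("degenerate tree: all branch lengths are zero; ",
                "returning the input rooting")
        return(tree)
    }
    # a node label is a statement about the subtree below that node under
    # the input rooting; transfer labels by that subtree's tip set, so a
    # node whose subtree is unchanged by re-rooting keeps its support and
    # a node created or flipped by re-rooting has unknown (not zero)
    # support — unknown conservatively fails the clade-founding threshold
    sup <- nodeSupports(tree)
    splitKeys <- function(tr) {
        ntip <- Ntip(tr)
        ds <- Descendants(tr, (ntip + 1L):(ntip + tr$Nnode), "tips")
        vapply(ds, function(i)
            paste(sort(tr$tip.label[i]), collapse = "\r"), "")
    }
    lut <- setNames(sup, splitKeys(tree))
    lut <- lut[!is.na(lut)]
    mid <- phangorn::midpoint(tree, node.labels = "delete")
    newsup <- unname(lut[splitKeys(mid)])
    mid$node.label <- ifelse(is.na(newsup), "", as.character(newsup))
    mid
}

#' Partition a rooted tree into clades
#'
#' Implements the support/branch-length clade rule: internal nodes are
#' visited in pre-order, and a node founds a clade when its bootstrap
#' support is at least `supportMin` and the mean root-to-tip path length
#' over its subtree's tips exceeds `brlMin` (deep, long-branch subtrees
#' split off). Descendants of a founded clade are not re-cut. Tips not
#' captured by any founding node form a residual clade. Nodes with no
#' support label never found a clade (unknown support fails the
#' threshold). Clades are labelled C1..Ck in pre-order; manual overrides
#' (label -> tip set, resolved to the tips' most recent common ancestor)
#' take precedence over the rule and keep their own labels.
#'
#' @param tree a rooted [ape::phylo] tree (see [midpointRoot()]).
#' @param thresholds an [NLRThresholds-class] object (`brlMin`,
#'   `supportMin`).
#' @param overrides optional named list: clade label -> character vector
#'   of tip ids whose MRCA founds that clade. Unknown tips are an error.
#' @return A [CladePartition-class] object.
#' @export
partitionClades <- function(tree, thresholds = NLRThresholds(),
                            overrides = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (!is.rooted(tree))
        stopValidation("partitionClades needs a rooted tree")
    ntip <- Ntip(tree)
    sup <- nodeSupports(tree)
    depth <- node.depth.edgelength(tree)  # root-to-node path lengths
    tipSets <- Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), "tips")
    tr <- stats::reorder(tree, "cladewise")
    preorder <- unique(as.vector(t(tr$edge)))
    preorderInt <- preorder[preorder > ntip]

    forcedNode <- integer(0)
    if (!is.null(overrides)) {
        if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
            stopValidation("overrides must be a named list")
        forcedNode <- vapply(overrides, function(tips) {
            bad <- setdiff(tips, tree$tip.label)
            if (length(bad))
                stopValidation("override names unknown tip(s): ",
                               paste(bad, collapse = ", "))
            if (length(tips) == 1L)
                match(tips, tree$tip.label)
            else as.integer(getMRCA(tree, tips))
        }, 1L)
    }

    cladeLabel <- rep(NA_character_, ntip)
    founding <- integer(0)
    covered <- rep(FALSE, ntip + tree$Nnode)
    found <- function(node, label) {
        tips <- if (node <= ntip) node else tipSets[[node - ntip]]
        cladeLabel[tips] <<- label
        covered[tips] <<- TRUE
        if (node > ntip) {
            below <- unlist(Descendants(tree, node, "all"))
            covered[c(node, below)] <<- TRUE
        }
        founding[label] <<- node
    }
    for (i in seq_along(forcedNode))
        found(forcedNode[i], names(forcedNode)[i])

    k <- 0L
    for (node in preorderInt) {
        if (covered[node]) next
        s <- sup[node - ntip]
        if (is.na(s) || s < thresholds@supportMin) next
        tips <- tipSets[[node - ntip]]
        if (mean(depth[tips]) > thresholds@brlMin) {
            k <- k + 1L
            found(node, paste0("C", k))
        }
    }
    if (anyNA(cladeLabel))
        cladeLabel[is.na(cladeLabel)] <- paste0("C", k + 1L)
    new("CladePartition",
        cladeOf = setNames(cladeLabel, tree$tip.label),
        ruleParams = list(brlMin = thresholds@brlMin,
                          supportMin = thresholds@supportMin),
        foundingNodes = founding)
}

#' Per-clade integrated-domain summaries
#'
#' For every clade: tip count, tips carrying at least one strict ID, the
#' percentage (truncated to two decimals, the printed-table convention),
#' the non-redundant union of strict ID family names, and the clade's
#' share of all ID-bearing NLRs (the statistic behind "one clade accounts
#' for nearly 30% of all NLR-IDs").
#'
#' @param partition a [CladePartition-class] object.
#' @param records classification DataFrame from [classifyNLRSet()]; every
#'   tip of the partition must have a row (matched by protein_id).
#' @return data.frame with columns clade, n_tips, n_with_id, pct_with_id,
#'   n_id_domains, id_domains, share_of_ids.
#' @export
cladeSummaries <- function(partition, records) {
    co <- cladeOf(partition)
    idx <- match(names(co), records$protein_id)
    if (anyNA(idx))
        stopValidation("tip(s) without an NLR record: ",
                       paste(head(names(co)[is.na(idx)], 5L),
                             collapse = ", "))
    hasId <- lengths(records$ids_strict[idx]) > 0L
    doms <- records$ids_strict[idx]
    clades <- sort(unique(co))
    rows <- lapply(clades, function(cl) {
        in_cl <- co == cl
        u <- sort(unique(unlist(doms[in_cl])))
        data.frame(clade = cl, n_tips = sum(in_cl),
                   n_with_id = sum(hasId & in_cl),
                   pct_with_id = pctTrunc(sum(hasId & in_cl), sum(in_cl)),
                   n_id_domains = length(u),
                   id_domains = paste(u, collapse = ","),
                   share_of_ids = pctTrunc(sum(hasId & in_cl),
                                           sum(hasId)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Tree-viewer annotation table for a partition
#'
#' Plain tab-separated annotation usable by interactive tree viewers: tip
#' label, clade, a stable clade colour, and an ID-presence flag.
#'
#' @param partition a [CladePartition-class] object.
#' @param records classification DataFrame from [classifyNLRSet()].
#' @return data.frame with columns tip, clade, color, has_id.
#' @export
cladeAnnotationTable <- function(partition, records) {
    co <- cladeOf(partition)
    idx <- match(names(co), records$protein_id)
    pal <- grDevices::hcl.colors(max(3L, length(unique(co))), "Dark 3")
    col <- pal[match(co, sort(unique(co)))]
    data.frame(tip = names(co), clade = unname(co), color = col,
               has_id = !is.na(idx) & lengths(records$ids_strict[idx]) > 0L)
}
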