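#' Translate a variant centroid to protein
#'
#' Standard-code translation of a chosen reading frame. With
#' \code{frame = "auto"} the frame with the fewest internal stop codons is
#' chosen (ties broken towards the lowest frame index), matching the
#' expectation that a genuine biosynthetic-domain amplicon has an open
#' frame. Internal stops are retained as \code{*} symbols.
#'
#' @param centroid DNA string (length >= 3 after the frame offset).
#' @param frame 0, 1, 2 or \code{"auto"}.
#' @return Amino-acid string; the chosen frame is attached as attribute
#'   \code{"frame"}.
#' @export
translate_variant <- function(centroid, frame = "auto") {
  centroid <- toupper(as.character(centroid))
  tr1 <- function(f) {
    s <- substr(centroid, f + 1L, nchar(centroid))
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return(NULL)
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, n)),
      if.fuzzy.codon = "X"))
  }
  if (identical(frame, "auto")) {
    cand <- lapply(0:2, tr1)
    if (all(vapply(cand, is.null, TRUE)))
      stop("sequence too short to translate")
    stops <- vapply(cand, function(p) {
      if (is.null(p)) return(Inf)
      body <- substr(p, 1L, nchar(p) - 1L)   # terminal stop is not internal
      lengths(regmatches(body, gregexpr("*", body, fixed = TRUE)))
    }, numeric(1))
    frame <- which.min(stops) - 1L
  }
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2)
  p <- tr1(frame)
  if (is.null(p)) stop("sequence too short to translate")
  structure(p, frame = frame)
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Best local protein alignment with identity and coverage
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1). Reports the best hit's identity (identical columns over all
#' alignment columns), query coverage (aligned query residues over query
#' length) and the matched target interval; a hit covering less than
#' \code{min_cov} of the query is discarded.
#'
#' @param query,target Non-empty amino-acid strings (stops as \code{*} are
#'   tolerated and replaced by \code{X} for alignment).
#' @param min_cov Minimum query coverage (default 0.80).
#' @return A list \code{identity}, \code{query_coverage},
#'   \code{target_start}, \code{target_end} (0-based half-open), or
#'   \code{NULL} when no hit passes coverage.
#' @export
align_identity <- function(query, target, min_cov = 0.80) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  q <- gsub("*", "X", as.character(query), fixed = TRUE)
  t <- gsub("*", "X", as.character(target), fixed = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q), subject = Biostrings::AAString(t),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  pr <- aln@pattern@range
  sr <- aln@subject@range
  cov <- IRanges::width(pr) / nchar(q)
  if (length(cov) == 0L || cov < min_cov) return(NULL)
  list(identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
       query_coverage = cov,
       target_start = IRanges::start(sr) - 1L,
       target_end = IRanges::end(sr))
}

#' Read reference BGC proteins from FASTA
#'
#' Headers follow the convention \code{>bgc_id|protein_id}; all proteins
#' sharing a \code{bgc_id} form one reference cluster.
#'
#' @param path Protein FASTA path.
#' @return A named list of references, each a list \code{bgc_id},
#'   \code{proteins} (named character vector of amino-acid strings).
#' @export
read_reference_bgcs <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bgc <- vapply(parts, `[`, "", 1L)
  prot <- vapply(parts, function(p) paste(p[-1L], collapse = "|"), "")
  seqs <- as.character(aa)
  out <- lapply(split(seq_along(seqs), bgc), function(idx) {
    p <- seqs[idx]; names(p) <- prot[idx]
    list(bgc_id = bgc[idx[1L]], proteins = p)
  })
  out[order(names(out))]
}

## Candidate matches of every network node against a set of target proteins.
## Returns a list per node of data.frames (target, start, end, identity).
.gather_candidates <- function(net, proteins, min_cov = 0.80,
                               frame = "auto") {
  lapply(seq_len(nrow(net$nodes)), function(i) {
    qaa <- tryCatch(translate_variant(net$nodes$centroid[i], frame = frame),
                    error = function(e) NULL)
    hits <- list()
    if (!is.null(qaa)) {
      for (pi in seq_along(proteins)) {
        h <- align_identity(qaa, proteins[[pi]], min_cov = min_cov)
        if (!is.null(h))
          hits[[length(hits) + 1L]] <- data.frame(
            target = names(proteins)[pi], start = h$target_start,
            end = h$target_end, identity = h$identity)
      }
    }
    if (length(hits) == 0L)
      data.frame(target = character(), start = integer(), end = integer(),
                 identity = numeric())
    else do.call(rbind, hits)
  })
}

## TRUE when two claimed target intervals conflict: same protein and
## reciprocal overlap above frac (overlap exceeding frac of BOTH intervals).
.claims_conflict <- function(c1, c2, frac = 0.25) {
  if (c1$target != c2$target) return(FALSE)
  ov <- min(c1$end, c2$end) - max(c1$start, c2$start)
  if (ov <= 0) return(FALSE)
  ov > frac * (c1$end - c1$start) && ov > frac * (c2$end - c2$start)
}

## Exact best assignment: at most one candidate per node, maximising total
## identity subject to pairwise non-conflict. Branch-and-bound over nodes
## ordered by decreasing best candidate; exact for the network sizes this
## pipeline produces (tens of nodes, few candidates each).
.best_assignment <- function(candidates, overlap_frac = 0.25) {
  n <- length(candidates)
  best_per_node <- vapply(candidates, function(d)
    if (nrow(d) > 0L) max(d$identity) else 0, numeric(1))
  ord <- order(-best_per_node)
  best <- list(total = -1, pick = integer(n))
  suffix_bound <- rev(cumsum(rev(best_per_node[ord])))
  pick <- integer(n)   # 0 = unmatched, else candidate row in node's table
  recurse <- function(k, total, chosen) {
    if (k > n) {
      if (total > best$total) best <<- list(total = total, pick = pick)
      return()
    }
    if (total + suffix_bound[k] <= best$total) return()
    node <- ord[k]
    cand <- candidates[[node]]
    rows <- if (nrow(cand) > 0L) order(-cand$identity) else integer(0)
    for (r in rows) {
      claim <- cand[r, , drop = FALSE]
      ok <- TRUE
      for (ch in chosen) {
        if (.claims_conflict(ch, claim, overlap_frac)) { ok <- FALSE; break }
      }
      if (ok) {
        pick[node] <<- r
        recurse(k + 1L, total + cand$identity[r],
                c(chosen, list(claim)))
        pick[node] <<- 0L
      }
    }
    recurse(k + 1L, total, chosen)   # leave node unmatched
  }
  recurse(1L, 0, list())
  assigned <- numeric(n)
  for (i in seq_len(n)) {
    if (best$pick[i] > 0L)
      assigned[i] <- candidates[[i]]$identity[best$pick[i]]
  }
  assigned
}

#' Score a domain network against one reference BGC
#'
#' Every node's translated centroid is searched against all proteins of the
#' reference; the best combination of matches is chosen exactly, maximising
#' total identity under the constraint that no two nodes claim
#' substantially overlapping positions (over 25% reciprocal overlap) on the
#' same protein — i.e. the domains must match independent positions. If at
#' least \code{min_match_frac} of the network's domains are assigned, the
#' similarity score is the median percent identity over ALL network
#' domains, unmatched domains entering as 0 (set
#' \code{count_unmatched = FALSE} to take the median over matched domains
#' only); otherwise the pair is classified unrelated with no score.
#'
#' @param net A \code{domain_network} with centroids.
#' @param ref A reference from [read_reference_bgcs()] (list with
#'   \code{bgc_id}, \code{proteins}).
#' @param min_match_frac Minimum matched fraction for relatedness
#'   (default 0.5).
#' @param min_cov Query coverage gate per hit (default 0.80).
#' @param count_unmatched Include unmatched domains as identity-0 entries
#'   in the median (default \code{TRUE}).
#' @return A list \code{network_id}, \code{target_id},
#'   \code{matched_fraction}, \code{score} (percent, \code{NA} when
#'   unrelated), \code{classification} (\code{"related"}/\code{"unrelated"})
#'   and \code{assigned} (per-node identities).
#' @export
score_network_vs_reference <- function(net, ref, min_match_frac = 0.5,
                                       min_cov = 0.80,
                                       count_unmatched = TRUE) {
  stopifnot(inherits(net, "domain_network"))
  cand <- .gather_candidates(net, ref$proteins, min_cov = min_cov)
  assigned <- .best_assignment(cand)
  mf <- mean(assigned > 0)
  if (mf >= min_match_frac) {
    vals <- if (count_unmatched) assigned else assigned[assigned > 0]
    score <- stats::median(vals) * 100
    cls <- "related"
  } else {
    score <- NA_real_
    cls <- "unrelated"
  }
  list(network_id = net$network_id, target_id = ref$bgc_id,
       matched_fraction = mf, score = score, classification = cls,
       assigned = assigned)
}

#' Classify a network as known or novel
#'
#' A network is \code{"known"} when any related reference comparison
#' reaches \code{known_identity} percent median identity; otherwise it is
#' \code{"novel"} — including the case of no related references at all.
#'
#' @param results List of results from [score_network_vs_reference()] for
#'   one network.
#' @param known_identity Percent identity threshold (default 75).
#' @return \code{"known"} or \code{"novel"}.
#' @export
classify_novelty <- function(results, known_identity = 75) {
  scores <- vapply(results, function(r)
    if (identical(r$classification, "related")) r$score else NA_real_,
    numeric(1))
  if (any(!is.na(scores) & scores >= known_identity)) "known" else "novel"
}

#' Are two domain networks closely related?
#'
#' Evaluated from \code{net_a}'s side (asymmetric): \code{net_b}'s
#' translated domains serve as targets, each claimable by at most one of
#' \code{net_a}'s domains, and the networks are closely related when at
#' least \code{min_match_frac} of \code{net_a}'s domains are assigned a
#' match of at least \code{min_identity} percent identity.
#'
#' @param net_a,net_b \code{domain_network} objects with centroids.
#' @param min_match_frac Fraction of \code{net_a} domains required
#'   (default 0.5).
#' @param min_identity Percent identity per matched domain (default 90).
#' @param min_cov Query coverage gate (default 0.80).
#' @return \code{TRUE} when closely related.
#' @export
compare_networks <- function(net_a, net_b, min_match_frac = 0.5,
                             min_identity = 90, min_cov = 0.80) {
  stopifnot(inherits(net_a, "domain_network"),
            inherits(net_b, "domain_network"))
  targets <- vapply(seq_len(nrow(net_b$nodes)), function(i)
    as.character(tryCatch(
      translate_variant(net_b$nodes$centroid[i]),
      error = function(e) "")), "")
  names(targets) <- net_b$nodes$variant_id
  targets <- targets[nchar(targets) > 0L]
  if (length(targets) == 0L) return(FALSE)
  cand <- .gather_candidates(net_a, as.list(targets), min_cov = min_cov)
  # only identities clearing the per-domain threshold can support
  # relatedness; filtering first keeps the assignment aimed at them
  cand <- lapply(cand, function(d)
    d[d$identity * 100 >= min_identity, , drop = FALSE])
  assigned <- .best_assignment(cand)
  mean(assigned * 100 >= min_identity & assigned > 0) >= min_match_frac
}

#' Validate a network's clustering prediction against an assembled contig
#'
#' Each node's centroid is searched at the nucleotide level against both
#' strands of the contig (local alignment, full-query coverage at least
#' \code{min_cov}); nodes reaching \code{id_threshold} identity are counted
#' as validated clustering predictions, the rest as false predictions.
#'
#' @param net A \code{domain_network} with centroids.
#' @param contig DNA string of the assembled clone/contig.
#' @param id_threshold Nucleotide identity threshold (default 0.93).
#' @param min_cov Query coverage (default 0.80).
#' @return A list \code{validated}, \code{false} with
#'   \code{validated + false == nrow(net$nodes)}.
#' @export
validate_network_on_contig <- function(net, contig, id_threshold = 0.93,
                                       min_cov = 0.80) {
  stopifnot(inherits(net, "domain_network"), nchar(contig) > 0L)
  targets <- c(fwd = as.character(contig),
               rev = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(contig))))
  ok <- vapply(net$nodes$centroid, function(q) {
    for (t in targets) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(q),
        subject = Biostrings::DNAString(t),
        type = "local", substitutionMatrix = .nuc_submat(),
        gapOpening = 2, gapExtension = 1)
      cov <- IRanges::width(aln@pattern@range) / nchar(q)
      idy <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      if (length(cov) == 1L && cov >= min_cov && idy >= id_threshold)
        return(TRUE)
    }
    FALSE
  }, logical(1))
  list(validated = sum(ok), false = sum(!ok))
}
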