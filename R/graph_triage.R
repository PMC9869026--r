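## Assembly-graph topology triage: parse GFA1, classify connected
## components as circular / tangled-circular / linear, extract circular
## contigs (trimming the self-link overlap), emit tangle members for
## external re-assembly, and produce the pre-binning linear contig set.

#' Parse a GFA1 assembly graph
#'
#' Reads S (segment) and L (link) records.  Other record types are ignored
#' with a warning.  A link that references a segment with no S record is a
#' format error.
#'
#' @param path GFA1 file.
#' @return object of class `assembly_graph`: list with `segments`
#'   (data.frame id/length/depth), `seqs` (named character) and `links`
#'   (data.frame from/from_orient/to/to_orient/overlap).
#' @export
parse_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  ln <- readLines(path)
  rectype <- substring(ln, 1, 1)
  unknown <- setdiff(unique(rectype), c("S", "L", "H", ""))
  if (length(unknown))
    warning("ignoring GFA record types: ", paste(unknown, collapse = ", "))
  segs <- strsplit(ln[rectype == "S"], "\t", fixed = TRUE)
  ids <- vapply(segs, `[`, "", 2)
  seqs <- vapply(segs, `[`, "", 3)
  lens <- ifelse(seqs == "*", NA_integer_, nchar(seqs))
  depth <- rep(NA_real_, length(segs))
  for (i in seq_along(segs)) {
    tags <- segs[[i]][-(1:3)]
    lntag <- grep("^LN:i:", tags, value = TRUE)
    if (length(lntag) && is.na(lens[i]))
      lens[i] <- as.integer(sub("^LN:i:", "", lntag[1]))
    dptag <- grep("^(dp|DP):f:", tags, value = TRUE)
    if (length(dptag)) depth[i] <- as.numeric(sub("^(dp|DP):f:", "", dptag[1]))
  }
  if (anyDuplicated(ids)) stop("duplicate segment ids in ", path)
  lrec <- which(rectype == "L")
  links <- if (length(lrec)) {
    parts <- strsplit(ln[lrec], "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) < 6)
    if (length(bad))
      stop("malformed L record at line ", lrec[bad[1]])
    df <- data.frame(from = vapply(parts, `[`, "", 2),
                     from_orient = vapply(parts, `[`, "", 3),
                     to = vapply(parts, `[`, "", 4),
                     to_orient = vapply(parts, `[`, "", 5),
                     overlap = vapply(parts, `[`, "", 6))
    miss <- !(df$from %in% ids) | !(df$to %in% ids)
    if (any(miss))
      stop("L record references missing segment at line ",
           lrec[which(miss)[1]])
    df
  } else data.frame(from = character(), from_orient = character(),
                    to = character(), to_orient = character(),
                    overlap = character())
  structure(list(segments = data.frame(id = ids, length = lens,
                                       depth = depth),
                 seqs = stats::setNames(seqs, ids), links = links),
            class = "assembly_graph")
}

#' Classify graph components into the three contig topologies
#'
#' Components are the connected components of the undirected segment graph.
#' A single segment whose two ends are joined by a same-orientation
#' self-link (`s + s +` or `s - s -`) is `circular`; a single segment with
#' no links is `linear`; everything else — any multi-segment component,
#' and single segments with only palindromic (`s + s -`) self-links — is
#' `tangled_circular`.  A `has_cycle` flag records whether the component's
#' link graph actually contains a cycle.
#'
#' @param graph an [parse_gfa()] result.
#' @return data.frame of component calls: `component_id`, `topology`,
#'   `n_segments`, `total_bp`, `has_cycle`, `members` (list-column),
#'   ordered by `component_id`.
#' @export
classify_components <- function(graph) {
  stopifnot(inherits(graph, "assembly_graph"))
  ids <- graph$segments$id
  g <- igraph::graph_from_data_frame(
    graph$links[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership
  calls <- lapply(split(names(memb), memb), function(members) {
    members <- sort(members)
    n <- length(members)
    lk <- graph$links[graph$links$from %in% members |
                        graph$links$to %in% members, , drop = FALSE]
    self_ht <- lk$from == lk$to & lk$from_orient == lk$to_orient
    topo <- if (n == 1L) {
      if (nrow(lk) == 0) "linear"
      else if (any(self_ht)) "circular"
      else "tangled_circular"
    } else "tangled_circular"
    data.frame(topology = topo, n_segments = n,
               total_bp = sum(graph$segments$length[match(members, ids)]),
               has_cycle = nrow(lk) >= n,
               members = I(list(members)))
  })
  out <- do.call(rbind, calls)
  lead <- vapply(out$members, `[`, "", 1)
  out <- out[order(lead), , drop = FALSE]
  out <- cbind(component_id = sprintf("comp%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

## Parse an exact-match overlap CIGAR ("0M", "100M"); anything else raises.
overlap_from_cigar <- function(cigar) {
  if (!grepl("^[0-9]+M$", cigar))
    stop("unsupported overlap CIGAR '", cigar,
         "': only exact match lengths (e.g. 100M) are handled")
  as.integer(sub("M$", "", cigar))
}

#' Extract circular contigs
#'
#' Emits one sequence per circular component of at least `min_length_bp`,
#' with the duplicated head/tail overlap given by the self-link's CIGAR
#' trimmed off the end.
#'
#' @param graph an [parse_gfa()] result.
#' @param calls a [classify_components()] table.
#' @param min_length_bp minimum emitted (trimmed) length; default 0.
#' @return named character vector of circular contig sequences.
#' @export
extract_circular <- function(graph, calls, min_length_bp = 0) {
  circ <- calls[calls$topology == "circular", , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(circ))) {
    seg <- circ$members[[i]][1]
    lk <- graph$links[graph$links$from == seg & graph$links$to == seg &
                        graph$links$from_orient == graph$links$to_orient, ,
                      drop = FALSE]
    ov <- overlap_from_cigar(lk$overlap[1])
    sq <- graph$seqs[[seg]]
    if (sq == "*") stop("segment ", seg, " has no stored sequence")
    if (ov > 0) sq <- substring(sq, 1, nchar(sq) - ov)
    if (nchar(sq) >= min_length_bp) out[[seg]] <- sq
  }
  out
}

#' Member segments of a tangled component
#'
#' Returns the member sequences of one tangled-circular component so that
#' an external assembler can re-assemble them; requesting any other
#' topology is a usage error.
#'
#' @param graph an [parse_gfa()] result.
#' @param calls a [classify_components()] table.
#' @param component_id id of a `tangled_circular` component.
#' @return named character vector of member segment sequences.
#' @export
members_for_reassembly <- function(graph, calls, component_id) {
  row <- calls[calls$component_id == component_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown component '", component_id, "'")
  if (row$topology != "tangled_circular")
    stop("component '", component_id, "' is ", row$topology,
         ", not tangled_circular")
  members <- row$members[[1]]
  stats::setNames(as.character(graph$seqs[members]), members)
}

#' Pre-binning linear contig set
#'
#' Removes all circular and tangled components and keeps linear segments of
#' at least `min_contig_bp` (default 2000, the usual binning floor).
#'
#' @param graph an [parse_gfa()] result.
#' @param calls a [classify_components()] table.
#' @param min_contig_bp minimum contig length to keep.
#' @return named character vector of linear contig sequences.
#' @export
prebinning_filter <- function(graph, calls, min_contig_bp = 2000) {
  lin <- calls[calls$topology == "linear", , drop = FALSE]
  segs <- vapply(lin$members, `[`, "", 1)
  if (length(segs) == 0) return(stats::setNames(character(0), character(0)))
  lens <- graph$segments$length[match(segs, graph$segments$id)]
  keep <- segs[lens >= min_contig_bp]
  stats::setNames(as.character(graph$seqs[keep]), keep)
}

#' Write a component table
#'
#' @param calls a [classify_components()] table.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_component_table <- function(calls, path) {
  df <- calls[, c("component_id", "topology", "n_segments", "total_bp",
                  "has_cycle")]
  df$members <- vapply(calls$members, paste, "", collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
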