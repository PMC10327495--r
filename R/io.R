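# Interchange formats: canonical JSON graph documents, GFA v1, block x
# genome presence/absence, per-block gapped MSAs.

GRAPH_SCHEMA_VERSION <- "1.0"

# Deterministic relabelling: blocks sorted by their first occurrence along
# the lexicographically first path that visits them; paths sorted by name.
canonical_block_order <- function(graph) {
  pn <- sort(names(graph$paths))
  first_seen <- list()
  rank <- 0L
  for (nm in pn) {
    for (nid in graph$paths[[nm]]$nodes) {
      bid <- graph$nodes[[nid]]$block
      if (is.null(first_seen[[bid]])) {
        rank <- rank + 1L
        first_seen[[bid]] <- rank
      }
    }
  }
  ord <- names(first_seen)[order(unlist(first_seen))]
  stats::setNames(sprintf("PC%06d", seq_along(ord)), ord)
}

#' Serialize a pangraph to its JSON document
#'
#' Block ids are relabelled deterministically (`PC000001`, ... in order of
#' first occurrence along name-sorted paths), so equal graphs serialize to
#' byte-identical documents regardless of construction order.
#'
#' @param graph A `pangraph`.
#' @param provenance Optional named list recorded verbatim in the
#'   document.
#' @return A JSON string.
#' @export
pangraph_to_json <- function(graph, provenance = NULL) {
  relab <- canonical_block_order(graph)
  pn <- sort(names(graph$paths))
  # occurrence index of each node within its path
  occ_index <- list()
  for (nm in pn) {
    nds <- graph$paths[[nm]]$nodes
    for (i in seq_along(nds)) occ_index[[nds[i]]] <- i
  }
  edits_doc <- function(ed) {
    list(
      subs = purrr::map2(ed$sub_pos, ed$sub_base,
                         function(p, b) list(pos = p, base = b)),
      ins = purrr::map2(ed$ins_pos, ed$ins_seq,
                        function(p, s) list(pos = p, seq = s)),
      dels = purrr::map2(ed$del_pos, ed$del_len,
                         function(p, l) list(pos = p, len = l)))
  }
  blocks_doc <- lapply(names(relab), function(bid) {
    b <- graph$blocks[[bid]]
    nids <- names(b$nodes)
    ord <- order(vapply(nids, function(n) graph$nodes[[n]]$path, character(1)),
                 vapply(nids, function(n) occ_index[[n]], integer(1)))
    occs <- lapply(nids[ord], function(nid) {
      nd <- graph$nodes[[nid]]
      list(path = nd$path, step = occ_index[[nid]], strand = nd$strand,
           edits = edits_doc(b$nodes[[nid]]))
    })
    list(id = unname(relab[[bid]]), consensus = b$consensus,
         occurrences = occs)
  })
  paths_doc <- lapply(pn, function(nm) {
    p <- graph$paths[[nm]]
    steps <- lapply(p$nodes, function(nid) {
      nd <- graph$nodes[[nid]]
      list(block = unname(relab[[nd$block]]), strand = nd$strand)
    })
    list(name = nm, circular = p$circular, offset = p$offset %||% 0L,
         steps = steps)
  })
  doc <- list(schema_version = GRAPH_SCHEMA_VERSION,
              provenance = provenance %||% list(tool = "pancontig"),
              pancontigs = blocks_doc, paths = paths_doc)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
}

#' Write a pangraph JSON document to a file
#' @param graph A `pangraph`.
#' @param path Output file.
#' @param provenance Optional named list recorded in the document.
#' @return `path`, invisibly.
#' @export
write_pangraph_json <- function(graph, path, provenance = NULL) {
  writeLines(pangraph_to_json(graph, provenance), path, useBytes = TRUE)
  invisible(path)
}

json_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("invalid graph document: missing field '", field, "' at ", where)
  x[[field]]
}

#' Parse a pangraph from its JSON document
#'
#' @param text A JSON string, or a file path when `file = TRUE`.
#' @param file Read `text` as a path?
#' @return A `pangraph`.
#' @export
pangraph_from_json <- function(text, file = FALSE) {
  doc <- jsonlite::fromJSON(if (file) text else I(text), simplifyVector = FALSE)
  ver <- json_field(doc, "schema_version", "$")
  if (!identical(ver, GRAPH_SCHEMA_VERSION))
    stop("graph schema version mismatch: got ", ver,
         ", expected ", GRAPH_SCHEMA_VERSION)
  pcs <- json_field(doc, "pancontigs", "$")
  pth <- json_field(doc, "paths", "$")
  paths <- list(); nodes <- list(); blocks <- list()
  node_id_of <- function(path, step) paste0(path, ":", step)
  for (p in pth) {
    nm <- json_field(p, "name", "paths[]")
    steps <- json_field(p, "steps", nm)
    nids <- vapply(seq_along(steps), function(i) node_id_of(nm, i), character(1))
    for (i in seq_along(steps)) {
      st <- steps[[i]]
      nodes[[nids[i]]] <- list(block = json_field(st, "block", nm),
                               path = nm,
                               strand = json_field(st, "strand", nm))
    }
    paths[[nm]] <- list(name = nm, nodes = nids,
                        circular = isTRUE(p$circular),
                        offset = as.integer(p$offset %||% 0L))
  }
  for (b in pcs) {
    bid <- json_field(b, "id", "pancontigs[]")
    occs <- json_field(b, "occurrences", bid)
    bn <- list()
    for (oc in occs) {
      nid <- node_id_of(json_field(oc, "path", bid), json_field(oc, "step", bid))
      ed <- json_field(oc, "edits", bid)
      bn[[nid]] <- make_edits(
        sub_pos = vapply(ed$subs, function(s) as.integer(s$pos), integer(1)),
        sub_base = vapply(ed$subs, function(s) as.character(s$base), character(1)),
        ins_pos = vapply(ed$ins, function(s) as.integer(s$pos), integer(1)),
        ins_seq = vapply(ed$ins, function(s) as.character(s$seq), character(1)),
        del_pos = vapply(ed$dels, function(s) as.integer(s$pos), integer(1)),
        del_len = vapply(ed$dels, function(s) as.integer(s$len), integer(1)))
      if (is.null(nodes[[nid]]))
        stop("invalid graph document: occurrence ", nid,
             " of block ", bid, " has no matching path step")
      if (nodes[[nid]]$block != bid)
        stop("invalid graph document: step/occurrence mismatch for ", nid)
    }
    blocks[[bid]] <- list(id = bid,
                          consensus = toupper(json_field(b, "consensus", bid)),
                          nodes = bn)
  }
  g <- new_pangraph(blocks, nodes, paths)
  validate_pangraph(g)
  g
}

#' Export a pangraph as GFA v1
#'
#' One `S` line per pancontig (consensus as the segment sequence), one `P`
#' line per genome with `+`/`-` orientations, and `L` lines with `0M`
#' overlap for every observed adjacency (including the circular wrap).
#'
#' @param graph A `pangraph`.
#' @return Character vector of GFA lines.
#' @export
pangraph_to_gfa <- function(graph) {
  relab <- canonical_block_order(graph)
  pn <- sort(names(graph$paths))
  s_lines <- vapply(names(relab), function(bid) {
    paste("S", relab[[bid]], graph$blocks[[bid]]$consensus, sep = "\t")
  }, character(1))
  p_lines <- vapply(pn, function(nm) {
    p <- graph$paths[[nm]]
    segs <- vapply(p$nodes, function(nid) {
      nd <- graph$nodes[[nid]]
      paste0(relab[[nd$block]], nd$strand)
    }, character(1))
    paste("P", nm, paste(segs, collapse = ","),
          paste(rep("0M", max(0L, length(segs) - 1L)), collapse = ","),
          sep = "\t")
  }, character(1))
  links <- character(0)
  for (nm in pn) {
    p <- graph$paths[[nm]]
    n <- length(p$nodes)
    if (n < 2L && !p$circular) next
    nxt <- c(seq_len(n)[-1L], if (p$circular && n > 1L) 1L else NA_integer_)
    for (i in seq_len(n)) {
      j <- nxt[i]
      if (is.na(j)) next
      a <- graph$nodes[[p$nodes[i]]]
      b <- graph$nodes[[p$nodes[j]]]
      links <- c(links, paste("L", relab[[a$block]], a$strand,
                              relab[[b$block]], b$strand, "0M", sep = "\t"))
    }
  }
  links <- sort(unique(links))
  c("H\tVN:Z:1.0", unname(s_lines), links, unname(p_lines))
}

#' Write GFA v1 to a file
#' @param graph A `pangraph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pangraph_gfa <- function(graph, path) {
  writeLines(pangraph_to_gfa(graph), path)
  invisible(path)
}

#' Block-by-genome presence/absence counts
#'
#' @param graph A `pangraph`.
#' @return A tibble: `block`, then one integer column per genome with the
#'   number of occurrences of the block in that genome.
#' @export
presence_absence <- function(graph) {
  relab <- canonical_block_order(graph)
  pn <- sort(names(graph$paths))
  rows <- lapply(names(relab), function(bid) {
    b <- graph$blocks[[bid]]
    paths <- vapply(names(b$nodes), function(nid) graph$nodes[[nid]]$path,
                    character(1))
    cnt <- table(factor(paths, levels = pn))
    out <- tibble::tibble(block = unname(relab[[bid]]))
    for (nm in pn) out[[nm]] <- as.integer(cnt[[nm]])
    out
  })
  dplyr::bind_rows(rows)
}

#' Write the presence/absence matrix as TSV
#' @param graph A `pangraph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(graph, path) {
  utils::write.table(presence_absence(graph), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gapped FASTA of one block's implied multiple alignment
#'
#' Rows realize the consensus-plus-edits alignment; ungapping a record
#' yields that member's reconstructed segment (consensus-forward frame).
#'
#' @param graph A `pangraph`.
#' @param block_id Block id (internal id, or canonical `PC...` label).
#' @return Named character vector of gapped rows (one per occurrence,
#'   named `<genome>:<step>`), with attribute `consensus_row`.
#' @export
export_block_msa <- function(graph, block_id) {
  if (!block_id %in% names(graph$blocks)) {
    relab <- canonical_block_order(graph)
    hit <- names(relab)[relab == block_id]
    if (length(hit) != 1L) stop("block not found: ", block_id)
    block_id <- hit
  }
  b <- graph$blocks[[block_id]]
  al <- block_alignment_matrix(b)
  rows <- apply(al$mat, 1L, paste, collapse = "")
  nm <- vapply(names(b$nodes), function(nid) {
    nd <- graph$nodes[[nid]]
    p <- graph$paths[[nd$path]]
    paste0(nd$path, ":", match(nid, p$nodes))
  }, character(1))
  names(rows) <- nm
  attr(rows, "consensus_row") <- paste(al$pattern, collapse = "")
  rows
}

#' Write a block MSA as gapped FASTA
#' @param graph A `pangraph`.
#' @param block_id Block id.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_block_msa <- function(graph, block_id, path) {
  rows <- export_block_msa(graph, block_id)
  write_fasta(stats::setNames(as.character(rows), names(rows)), path)
  invisible(path)
}
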