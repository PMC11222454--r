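# Machine-readable network export (Gephi-compatible) and edge-list TSV
# round-tripping.

network_node_table <- function(network) {
  st <- degree_stats(network)
  data.frame(id = st$id, type = st$type, degree = st$degree,
             betweenness = st$betweenness, stringsAsFactors = FALSE)
}

#' Write a strength network to file
#'
#' Formats: `edge-tsv` (source, source_type, target, target_type, strength,
#' retained), `graphml` and `gexf` (node attributes type/degree/betweenness,
#' edge attributes strength/retained).
#'
#' @param network a `StrengthNetwork`.
#' @param path output path.
#' @param format one of `"edge-tsv"`, `"graphml"`, `"gexf"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge-tsv", "graphml", "gexf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_invalid_parameter(
                       sprintf("unknown network format '%s'", format[1])))
  types <- setNames(network$nodes$type, network$nodes$id)
  arcs <- network$arcs
  if (format == "edge-tsv") {
    out <- data.frame(source = arcs$from,
                      source_type = unname(types[arcs$from]),
                      target = arcs$to,
                      target_type = unname(types[arcs$to]),
                      strength = arcs$strength,
                      retained = retained_flags(network),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }

  nt <- network_node_table(network)
  edf <- data.frame(from = arcs$from, to = arcs$to,
                    strength = if (nrow(arcs)) arcs$strength else numeric(0),
                    retained = retained_flags(network),
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = nt)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }

  # minimal static directed GEXF 1.3
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
    '  <graph defaultedgetype="directed">',
    '    <attributes class="node">',
    '      <attribute id="type" title="type" type="string"/>',
    '      <attribute id="degree" title="degree" type="integer"/>',
    '      <attribute id="betweenness" title="betweenness" type="double"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="strength" title="strength" type="double"/>',
    '      <attribute id="retained" title="retained" type="boolean"/>',
    '    </attributes>',
    '    <nodes>',
    sprintf(paste0('      <node id="%s" label="%s"><attvalues>',
                   '<attvalue for="type" value="%s"/>',
                   '<attvalue for="degree" value="%d"/>',
                   '<attvalue for="betweenness" value="%.10g"/>',
                   '</attvalues></node>'),
            esc(nt$id), esc(nt$id), esc(nt$type), nt$degree, nt$betweenness),
    '    </nodes>',
    '    <edges>',
    if (nrow(edf)) sprintf(paste0('      <edge id="e%d" source="%s" target="%s">',
                                  '<attvalues><attvalue for="strength" value="%.10g"/>',
                                  '<attvalue for="retained" value="%s"/>',
                                  '</attvalues></edge>'),
                           seq_len(nrow(edf)), esc(edf$from), esc(edf$to),
                           edf$strength, tolower(as.character(edf$retained)))
    else character(0),
    '    </edges>',
    '  </graph>',
    '</gexf>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a strength network from an edge-list TSV
#'
#' Counterpart of `write_network(format = "edge-tsv")`.
#'
#' @param path TSV path.
#' @param nodes optional node table (id, type) to carry isolated nodes.
#' @param timepoint optional time-point label.
#' @param B bootstrap count to record.
#' @return a `StrengthNetwork`.
#' @export
read_network_tsv <- function(path, nodes = NULL, timepoint = NA_character_, B = NA_integer_) {
  if (!file.exists(path)) stop_configuration(sprintf("missing network TSV: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "strength")
  if (!all(need %in% names(df)))
    stop_parse(sprintf("network TSV lacks columns: %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  if (is.null(nodes)) {
    nodes <- unique(data.frame(
      id = c(df$source, df$target),
      type = c(df$source_type, df$target_type),
      stringsAsFactors = FALSE))
  }
  arcs <- data.frame(from = df$source, to = df$target, strength = df$strength,
                     stringsAsFactors = FALSE)
  if ("retained" %in% names(df)) arcs$retained <- as.logical(df$retained)
  structure(list(arcs = arcs, nodes = nodes, timepoint = timepoint, B = B,
                 quartile_threshold = NA_real_),
            class = "StrengthNetwork")
}

#' Construct a strength network directly
#'
#' Mainly for assembling small networks in examples and tests.
#'
#' @param arcs data.frame `from`, `to`, optional `strength`, `retained`.
#' @param nodes data.frame `id`, `type`; inferred from arcs if omitted
#'   (ids starting with "miR" typed miRNA, others mRNA).
#' @param timepoint label.
#' @param B bootstrap count.
#' @return a `StrengthNetwork`.
#' @export
strength_network <- function(arcs, nodes = NULL, timepoint = NA_character_,
                             B = NA_integer_) {
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (!"strength" %in% names(arcs)) arcs$strength <- rep(1, nrow(arcs))
  if (is.null(nodes)) {
    ids <- unique(c(arcs$from, arcs$to))
    nodes <- data.frame(id = ids,
                        type = ifelse(grepl("^miR|^rno-|^hsa-", ids), "miRNA", "mRNA"),
                        stringsAsFactors = FALSE)
  }
  if (any(bad <- !(c(arcs$from, arcs$to) %in% nodes$id)))
    stop_invalid_input(sprintf("arc endpoint not in nodes: %s",
                               c(arcs$from, arcs$to)[bad][1]))
  structure(list(arcs = arcs, nodes = nodes, timepoint = timepoint, B = B,
                 quartile_threshold = NA_real_),
            class = "StrengthNetwork")
}
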