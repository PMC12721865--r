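# Diagnostic artefacts: an interactive HTML view of the similarity graph
# and a histogram of all non-zero pairwise scores.

#' Assemble a graph view for reporting
#'
#' @param labels All neighbourhood labels (pre-pruning input set).
#' @param organisms Organism per label.
#' @param kept Logical per label: survived pruning?
#' @param edges `data.frame` with columns `label_i`, `label_j`, `score`
#'   (the supra-threshold pruning graph).
#' @param threshold Active similarity threshold.
#' @return A `graph_view` object for [write_graph_html()].
#' @export
graph_view <- function(labels, organisms, kept, edges, threshold) {
  stopifnot(length(labels) == length(organisms),
            length(labels) == length(kept))
  structure(
    list(
      nodes = data.frame(label = labels, kept = kept,
                         organism = organisms, stringsAsFactors = FALSE),
      edges = data.frame(from = edges$label_i, to = edges$label_j,
                         weight = edges$score, stringsAsFactors = FALSE),
      threshold = threshold
    ),
    class = "graph_view"
  )
}

#' Write the similarity graph as a self-contained HTML page
#'
#' Nodes are labelled with the file stem; hovering shows the organism and
#' the kept/removed status; removed nodes are drawn in a distinct style;
#' edge labels show the similarity to two decimals. The graph drawn is
#' the supra-threshold pruning graph, so the kept/removed structure is
#' directly interpretable. The node/edge data is embedded as a JSON block
#' (`<script type="application/json" id="graph-data">`) and can be
#' re-extracted programmatically.
#'
#' @param view A [graph_view()].
#' @param path Output `.html` path.
#' @return `path`.
#' @export
write_graph_html <- function(view, path) {
  stopifnot(inherits(view, "graph_view"))
  payload <- jsonlite::toJSON(
    list(
      threshold = jsonlite::unbox(view$threshold),
      nodes = view$nodes,
      edges = view$edges
    ),
    digits = NA, auto_unbox = FALSE
  )
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>neighbourhood similarity graph</title>",
    "<style>",
    "  body { font-family: sans-serif; }",
    "  circle.kept { fill: #2b8cbe; }",
    "  circle.removed { fill: #bbbbbb; stroke: #888; stroke-dasharray: 3 2; }",
    "  line.edge { stroke: #d95f0e; stroke-width: 2; }",
    "  text.edge-label { font-size: 10px; fill: #d95f0e; }",
    "  text.node-label { font-size: 11px; }",
    "</style></head><body>",
    "<h2>Neighbourhood similarity graph</h2>",
    sprintf("<p>Edges join pairs whose similarity exceeds the threshold (%.2f). Grey dashed nodes were removed by pruning.</p>",
            view$threshold),
    sprintf("<script type=\"application/json\" id=\"graph-data\">%s</script>",
            as.character(payload)),
    "<svg id=\"graph\" width=\"900\" height=\"700\"></svg>",
    "<script>",
    graph_view_js(),
    "</script>",
    "</body></html>"
  )
  ok <- tryCatch({
    writeLines(html, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort_synsieve(sprintf("cannot write HTML to '%s'", path), "io")
  }
  path
}

# Minimal dependency-free renderer: circular layout, draggable nodes,
# tooltips via <title>. Layout is cosmetic only.
graph_view_js <- function() {
  paste(
    "var data = JSON.parse(document.getElementById('graph-data').textContent);",
    "var svg = document.getElementById('graph');",
    "var W = 900, H = 700, R = Math.min(W, H) / 2 - 80;",
    "var NS = 'http://www.w3.org/2000/svg';",
    "var pos = {};",
    "data.nodes.forEach(function (n, i) {",
    "  var a = 2 * Math.PI * i / data.nodes.length;",
    "  pos[n.label] = { x: W / 2 + R * Math.cos(a), y: H / 2 + R * Math.sin(a) };",
    "});",
    "data.edges.forEach(function (e) {",
    "  var p = pos[e.from], q = pos[e.to];",
    "  var l = document.createElementNS(NS, 'line');",
    "  l.setAttribute('class', 'edge');",
    "  l.setAttribute('x1', p.x); l.setAttribute('y1', p.y);",
    "  l.setAttribute('x2', q.x); l.setAttribute('y2', q.y);",
    "  svg.appendChild(l);",
    "  var t = document.createElementNS(NS, 'text');",
    "  t.setAttribute('class', 'edge-label');",
    "  t.setAttribute('x', (p.x + q.x) / 2); t.setAttribute('y', (p.y + q.y) / 2);",
    "  t.textContent = Number(e.weight).toFixed(2);",
    "  svg.appendChild(t);",
    "});",
    "data.nodes.forEach(function (n) {",
    "  var p = pos[n.label];",
    "  var c = document.createElementNS(NS, 'circle');",
    "  c.setAttribute('class', n.kept ? 'kept' : 'removed');",
    "  c.setAttribute('cx', p.x); c.setAttribute('cy', p.y);",
    "  c.setAttribute('r', 10);",
    "  var title = document.createElementNS(NS, 'title');",
    "  title.textContent = n.label + ' | ' + n.organism + ' | ' +",
    "    (n.kept ? 'kept' : 'removed');",
    "  c.appendChild(title);",
    "  svg.appendChild(c);",
    "  var t = document.createElementNS(NS, 'text');",
    "  t.setAttribute('class', 'node-label');",
    "  t.setAttribute('x', p.x + 12); t.setAttribute('y', p.y + 4);",
    "  t.textContent = n.label;",
    "  svg.appendChild(t);",
    "});",
    sep = "\n"
  )
}

#' Histogram of non-zero pairwise similarity scores
#'
#' Bins all non-zero pre-threshold scores into 20 fixed-width bins over
#' `(0, 1]`, draws a vertical line at the active threshold, and writes
#' both a PNG and the bin counts as `edge_histogram.csv` next to it.
#' This is the diagnostic used to judge how moving the similarity filter
#' would change the graph topology.
#'
#' @param weights Numeric vector of non-zero scores in `(0, 1]`.
#' @param path Output `.png` path (the CSV replaces the extension).
#' @param threshold Active similarity threshold (vertical marker).
#' @return `path`.
#' @export
write_edge_histogram <- function(weights, path, threshold) {
  breaks <- seq(0, 1, by = 0.05)
  if (length(weights)) {
    stopifnot(all(weights > 0), all(weights <= 1))
    counts <- graphics::hist(weights, breaks = breaks, right = TRUE,
                             include.lowest = TRUE, plot = FALSE)$counts
  } else {
    counts <- integer(20)
    log_line("INFO", "write_edge_histogram",
             "no non-zero pairwise scores; writing empty axes")
  }
  bins <- data.frame(
    bin_left = utils::head(breaks, -1),
    bin_right = utils::tail(breaks, -1),
    count = counts
  )
  csv_path <- sub("\\.png$", ".csv", path)
  utils::write.csv(bins, csv_path, row.names = FALSE)

  mids <- (bins$bin_left + bins$bin_right) / 2
  df <- data.frame(mid = mids, count = counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = 0.05, fill = "#2b8cbe", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "#d95f0e") +
    ggplot2::scale_x_continuous(limits = c(0, 1.001)) +
    ggplot2::labs(x = "pairwise similarity", y = "neighbourhood pairs") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150,
                  device = grDevices::png)
  path
}
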