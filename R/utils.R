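# Internal helpers shared across modules.

# Byte-order (C locale) sort so canonical names and tie-breaks are
# locale-independent.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_areatax <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "areatax_error")))
}

# Half-up rounding (round() in R is round-half-even, which disagrees with
# the reporting convention used for the percentage tables).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Topological order of a DAG given edges child -> parent; returns ids ordered
# so that every parent precedes its children.
topo_order_parents_first <- function(ids, child, parent) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = parent, to = child, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  as.character(igraph::topo_sort(g, mode = "out")$name)
}
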