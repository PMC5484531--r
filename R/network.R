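#' Build the IL interaction network at a significance tier
#'
#' Nodes are all parental ILs in the analysis (including ILs with zero
#' interactions, so denominators match the experiment); an edge connects
#' two ILs whose DIL reached at least the requested significance tier.
#' The graph is simple and undirected: no self-loops, and would-be
#' parallel edges (the same IL pair reaching the tier in several fits)
#' are collapsed to the edge with the smallest q-value.
#'
#' @param fits A `dil_epistasis_fits` tibble for a single phenotype,
#'   after [fdr_and_tiers()].
#' @param sterile_flags Tibble with columns `il` and `sterile` (from
#'   [classify_sterile()], filtered to the same phenotype). ILs absent
#'   from `fits` are retained as isolated nodes; ILs that parent no
#'   analyzable DIL are flagged `no_data`.
#' @param tier Minimum tier for an edge: `"highly-significant"` (default)
#'   or `"significant"`.
#' @return A `dmi_network` object: list with `nodes` (il, sterile,
#'   no_data), `edges` (il_a, il_b, direction, epsilon, q_value,
#'   architecture), `tier`, `phenotype`.
#' @examples
#' sets <- simulate_fitness_sets(6, eps = 0.6, model = "additive", seed = 3)
#' fits <- fdr_and_tiers(fit_epistasis(sets, seed = 3))
#' flags <- tibble::tibble(il = unique(c(sets$il_i, sets$il_j)),
#'                         sterile = FALSE)
#' build_network(fits, flags, tier = "significant")
#' @export
build_network <- function(fits, sterile_flags,
                          tier = c("highly-significant", "significant")) {
  tier <- match.arg(tier)
  if (!"tier" %in% names(fits))
    abort("fits lack a tier column; run fdr_and_tiers() first")
  phen <- unique(fits$phenotype[!is.na(fits$phenotype)])
  if (length(phen) > 1)
    abort("build the network from a single phenotype at a time")
  stopifnot(all(c("il", "sterile") %in% names(sterile_flags)))

  node_ids <- sort(unique(c(sterile_flags$il, fits$il_i, fits$il_j)))
  nodes <- tibble(il = node_ids) |>
    left_join(sterile_flags[, c("il", "sterile")], by = "il") |>
    mutate(sterile = !is.na(.data$sterile) & .data$sterile,
           no_data = !(.data$il %in% c(fits$il_i, fits$il_j)))

  sel <- fits[!is.na(fits$tier) & fits$tier >= tier, ]
  edges <- tibble(
    il_a = pmin(sel$il_i, sel$il_j),
    il_b = pmax(sel$il_i, sel$il_j),
    direction = sel$direction,
    epsilon = sel$epsilon,
    q_value = sel$q_value)
  if (any(edges$il_a == edges$il_b))
    abort("self-interaction edge encountered; DIL parents must differ")
  edges <- edges |>
    arrange(.data$il_a, .data$il_b, .data$q_value) |>
    distinct(.data$il_a, .data$il_b, .keep_all = TRUE)

  st <- setNames(nodes$sterile, nodes$il)
  edges$architecture <- classify_dmi(edges$direction,
                                     unname(st[edges$il_a]),
                                     unname(st[edges$il_b]))$architecture

  structure(list(nodes = nodes, edges = edges, tier = tier,
                 phenotype = if (length(phen)) phen else NA_character_),
            class = "dmi_network")
}

#' @export
print.dmi_network <- function(x, ...) {
  cat(sprintf("<dmi_network> %s, tier >= %s\n", x$phenotype, x$tier))
  cat(sprintf("  %d ILs (%d sterile), %d interaction edges\n",
              nrow(x$nodes), sum(x$nodes$sterile), nrow(x$edges)))
  invisible(x)
}

#' Convert an interaction network to an igraph object
#'
#' @param net A `dmi_network`.
#' @return An undirected `igraph` graph with node attribute `sterile` and
#'   edge attributes `direction`, `epsilon`, `q_value`, `architecture`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "dmi_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Degree and component summary of an interaction network
#'
#' Mean node degree overall and within the sterile / non-sterile node
#' classes, plus connected-component sizes (descending). An empty node
#' class yields a mean of 0 with a flag.
#'
#' @param net A `dmi_network`.
#' @return A list: `mean_degree`, `mean_degree_sterile`,
#'   `mean_degree_non_sterile`, `component_sizes`, `n_nodes`, `n_edges`,
#'   `empty_class` (character vector naming any empty node class).
#' @export
degree_summary <- function(net) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  sterile <- igraph::V(g)$sterile
  mean0 <- function(x) if (length(x)) mean(x) else 0
  comp <- igraph::components(g)
  empty <- c(if (!any(sterile)) "sterile", if (all(sterile)) "non-sterile")
  list(mean_degree = mean0(deg),
       mean_degree_sterile = mean0(deg[sterile]),
       mean_degree_non_sterile = mean0(deg[!sterile]),
       component_sizes = sort(unname(comp$csize), decreasing = TRUE),
       n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       empty_class = empty %||% character())
}

#' Classify the DMI architecture implied by one interaction
#'
#' Each observed interaction between two introgressions constrains the
#' architecture of the underlying Dobzhansky-Muller incompatibility, as a
#' pure function of the interaction direction and the parents' individual
#' sterility:
#' * synergistic epistasis, regardless of parental sterility, implies a
#'   higher-order DMI (a specific multi-allele combination is required
#'   for sterility);
#' * an antagonistic interaction between a sterile and a non-sterile IL
#'   indicates a pairwise DMI (phenotype rescue by complementation);
#' * an interaction of either direction between two sterile ILs implies a
#'   higher-order DMI or complex epistasis between two DMIs (a pairwise
#'   DMI would make only one parent sterile);
#' * an antagonistic interaction between two non-sterile ILs is left
#'   `undetermined` (no architecture is implied).
#'
#' @param direction Character vector, `"antagonistic"` or
#'   `"synergistic"`.
#' @param sterile_a,sterile_b Logical vectors: individual sterility of
#'   the two parent ILs.
#' @return A tibble with columns `architecture` (one of `pairwise-DMI`,
#'   `higher-order`, `higher-order-or-complex`, `undetermined`) and
#'   `rationale`.
#' @examples
#' classify_dmi(c("antagonistic", "synergistic", "antagonistic"),
#'              sterile_a = c(TRUE, FALSE, TRUE),
#'              sterile_b = c(FALSE, FALSE, TRUE))
#' @export
classify_dmi <- function(direction, sterile_a, sterile_b) {
  stopifnot(length(direction) == length(sterile_a),
            length(direction) == length(sterile_b))
  bad <- setdiff(unique(direction), c("antagonistic", "synergistic"))
  if (length(bad))
    abort(sprintf("unknown interaction direction(s): %s",
                  paste(bad, collapse = ", ")))
  if (length(direction) == 0)
    return(tibble(architecture = character(), rationale = character()))
  one <- function(d, sa, sb) {
    if (d == "synergistic") {
      c("higher-order",
        "synergistic epistasis requires a specific multi-allele combination")
    } else if (sa && sb) {
      c("higher-order-or-complex",
        "antagonism between two sterile ILs cannot be a single pairwise DMI")
    } else if (xor(sa, sb)) {
      c("pairwise-DMI",
        "rescue of a sterile IL by a non-sterile partner is complementation")
    } else {
      c("undetermined",
        "antagonism between two non-sterile ILs implies no architecture")
    }
  }
  res <- mapply(one, direction, sterile_a, sterile_b)
  tibble(architecture = unname(res[1, ]), rationale = unname(res[2, ]))
}

#' Export / import an interaction network
#'
#' `export_network()` writes the edge list as delimited text (columns
#' `phenotype`, `il_a`, `il_b`, `direction`, `epsilon`, `q_value`,
#' `architecture`) together with a companion `*_nodes` file holding the
#' node set and sterility flags, so that `read_network()` round-trips the
#' network losslessly (including isolated nodes). `format = "graphml"`
#' writes a single GraphML file with the same attribute names instead.
#'
#' @param net A `dmi_network`.
#' @param path Output path (edge-list file, or GraphML file).
#' @param format `"edgelist"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e)
    abort(sprintf("unknown format '%s'; supported: edgelist, graphml",
                  format[1])))
  stopifnot(inherits(net, "dmi_network"))
  if (format == "edgelist") {
    edges <- net$edges
    edges <- tibble(phenotype = net$phenotype, edges)
    write_delim_schema(edges, path, paste0("network-edges tier=", net$tier))
    npath <- nodes_path(path)
    write_delim_schema(tibble(phenotype = net$phenotype, net$nodes),
                       npath, "network-nodes")
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

nodes_path <- function(path) {
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  paste0(base, "_nodes", if (nzchar(ext)) paste0(".", ext) else "")
}

#' @rdname export_network
#' @param tier,phenotype Metadata restored onto the object when reading
#'   an edge list (`tier` defaults to the value recorded in the file
#'   header when present).
#' @export
read_network <- function(path, tier = NULL, phenotype = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(tier) && grepl("tier=", header))
    tier <- sub(".*tier=([a-z-]+).*", "\\1", header)
  edges <- as_tibble(read_delim_schema(path))
  nodes <- as_tibble(read_delim_schema(nodes_path(path)))
  phen <- phenotype %||% unique(c(edges$phenotype, nodes$phenotype))[1]
  structure(list(
    nodes = nodes[, c("il", "sterile", "no_data")],
    edges = edges[, c("il_a", "il_b", "direction", "epsilon", "q_value",
                      "architecture")],
    tier = tier %||% "highly-significant",
    phenotype = phen), class = "dmi_network")
}
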