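#' Typed guild-interaction template
#'
#' Container for the conceptual network that constrains which directed
#' causal links are tested: guild nodes with trophic-level attributes and
#' candidate directed links (driver -> driven) typed as `trophic`,
#' `non_trophic` or `hybrid` and directed `bottom_up` (resource drives
#' consumer), `top_down` (consumer drives resource) or `lateral`
#' (within-level, non-trophic).
#'
#' Validation enforces: no self-links; trophic and hybrid links present
#' in both orientations (all such links are bi-directional); non-trophic
#' links labelled `lateral`; `bottom_up`/`top_down` only on trophic or
#' hybrid links.
#'
#' @param nodes data frame with columns `guild`, `trophic_level`
#'   (`producer`, `grazer`/`intermediate`, `predator`/`consumer`) and
#'   optionally `class`.
#' @param links data frame with columns `driver`, `driven`,
#'   `interaction_type`, `trophic_direction`.
#' @return object of class `guild_graph`.
#' @export
guild_graph <- function(nodes, links) {
  stopifnot(all(c("guild", "trophic_level") %in% names(nodes)),
            all(c("driver", "driven", "interaction_type",
                  "trophic_direction") %in% names(links)))
  if (anyDuplicated(nodes$guild)) stop("duplicate guild ids")
  if (any(links$driver == links$driven)) stop("self-links are not allowed")
  unknown <- setdiff(unique(c(links$driver, links$driven)), nodes$guild)
  if (length(unknown)) stop("links reference unknown guilds: ",
                            paste(unknown, collapse = ", "))
  bad_type <- setdiff(unique(links$interaction_type),
                      c("trophic", "non_trophic", "hybrid"))
  if (length(bad_type)) stop("unknown interaction_type: ",
                             paste(bad_type, collapse = ", "))
  bad_dir <- setdiff(unique(links$trophic_direction),
                     c("bottom_up", "top_down", "lateral"))
  if (length(bad_dir)) stop("unknown trophic_direction: ",
                            paste(bad_dir, collapse = ", "))
  if (any(links$interaction_type == "non_trophic" &
          links$trophic_direction != "lateral"))
    stop("non-trophic links must be lateral")
  # trophic/hybrid links are bi-directional
  tr <- links[links$interaction_type %in% c("trophic", "hybrid"), ]
  if (nrow(tr)) {
    key <- paste(tr$driver, tr$driven)
    rkey <- paste(tr$driven, tr$driver)
    if (!all(rkey %in% key))
      stop("trophic/hybrid links must appear in both orientations")
  }
  if (anyDuplicated(paste(links$driver, links$driven)))
    stop("duplicate candidate links")
  structure(list(nodes = nodes, links = links), class = "guild_graph")
}

#' @export
print.guild_graph <- function(x, ...) {
  cat("guild_graph:", nrow(x$nodes), "guilds,",
      nrow(x$links), "candidate directed links\n")
  cat("  types:", paste(names(table(x$links$interaction_type)),
                        table(x$links$interaction_type),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Count candidate links, optionally by class
#'
#' @param graph a [guild_graph()].
#' @param interaction_type,trophic_direction optional filters.
#' @return integer count.
#' @export
n_candidate_links <- function(graph, interaction_type = NULL,
                              trophic_direction = NULL) {
  l <- graph$links
  if (!is.null(interaction_type)) l <- l[l$interaction_type %in% interaction_type, ]
  if (!is.null(trophic_direction)) l <- l[l$trophic_direction %in% trophic_direction, ]
  nrow(l)
}

#' Read a guild graph from plain-text files
#'
#' @param links_file TSV with columns `driver`, `driven`,
#'   `interaction_type`, `trophic_direction`.
#' @param nodes_file TSV with columns `guild`, `trophic_level`, `class`.
#' @return a [guild_graph()].
#' @export
read_guild_graph <- function(links_file, nodes_file) {
  guild_graph(read.delim(nodes_file, stringsAsFactors = FALSE),
              read.delim(links_file, stringsAsFactors = FALSE))
}

#' Write a guild graph to plain-text files
#'
#' @param graph a [guild_graph()].
#' @param links_file,nodes_file output TSV paths.
#' @return invisibly, the graph.
#' @export
write_guild_graph <- function(graph, links_file, nodes_file) {
  write.table(graph$links, links_file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(graph$nodes, nodes_file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(graph)
}
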