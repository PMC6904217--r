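#' Assemble an evolutionary trajectory along a line of descent
#'
#' Collects, at every node on the path from a chosen ancestor to a chosen
#' extant species, the reconstructed continuous trait values (from
#' [asr_ml()]) and the posterior probabilities of discrete characters (from
#' [simmap_summarize()] or [mk_marginal()]). The terminal record uses the
#' species' observed values where measured; reconstructed values are taken
#' node-wise with no interpolation along branches. Traits not reconstructed
#' for a node are emitted as missing, never interpolated.
#'
#' @param tree A `"phylo"` tree.
#' @param asr Named list of `"bm_asr"` objects (one per continuous trait).
#' @param posteriors Named list of `"simmap_summary"` objects or node x
#'   state probability matrices (one per discrete character).
#' @param ancestor Internal node id (e.g. from [mrca_node()]).
#' @param tip Tip label of the extant species.
#' @param observed Optional named list (per trait) of named vectors of
#'   observed tip values; defaults to the tip data inside each `"bm_asr"`.
#' @param present Named character vector: for each discrete character, the
#'   state whose probability is tracked (defaults from each summary).
#' @return Object of class `"trajectory"`: a data frame with one row per
#'   node (`node`, `label`, `age`, one column per trait, one `p_<char>`
#'   column per character), ages strictly decreasing.
#' @export
build_trajectory <- function(tree, asr = list(), posteriors = list(),
                             ancestor, tip, observed = NULL,
                             present = NULL) {
  path <- lineage_path(tree, ancestor, tip)
  out <- path
  tip_node <- path$node[nrow(path)]
  for (nm in names(asr)) {
    a <- asr[[nm]]
    ids <- map_nodes_to(a$tree, tree)
    est <- stats::setNames(a$nodes$estimate, ids[a$nodes$node])
    col <- est[as.character(path$node)]
    obs_v <- if (!is.null(observed[[nm]])) observed[[nm]] else a$tips
    col[nrow(path)] <- if (tip %in% names(obs_v)) obs_v[[tip]] else NA_real_
    out[[nm]] <- as.numeric(col)
  }
  for (nm in names(posteriors)) {
    po <- posteriors[[nm]]
    if (inherits(po, "simmap_summary")) {
      pres <- if (!is.null(present[nm]) && !is.na(present[nm]))
        present[[nm]] else po$present
      mat <- po$posterior
    } else {
      mat <- po
      pres <- present[[nm]]
      if (is.null(pres)) stop("supply `present` state for character ", nm)
    }
    out[[paste0("p_", nm)]] <- mat[as.character(path$node), pres]
  }
  structure(out, class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Evolutionary trajectory, ", nrow(x), " nodes, ",
      format(x$age[1L], digits = 5), " -> ",
      format(x$age[nrow(x)], digits = 5), " Myr\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Export a trajectory to long-format CSV
#'
#' One row per (node, variable); missing values are written as empty cells,
#' not zeros. Round-trips losslessly through [read_trajectory()].
#'
#' @param traj A `"trajectory"`.
#' @param file Output CSV path.
#' @return The long-format data frame, invisibly.
#' @export
export_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj) > 0L)
  vars <- setdiff(names(traj), c("node", "label", "age"))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(node = traj$node, label = traj$label, age = traj$age,
               variable = v, value = as.numeric(traj[[v]]))
  }))
  utils::write.csv(long, file, row.names = FALSE, na = "")
  invisible(long)
}

#' Read a trajectory written by [export_trajectory()]
#'
#' @param file CSV path.
#' @return A `"trajectory"` data frame (wide format).
#' @export
read_trajectory <- function(file) {
  long <- utils::read.csv(file, stringsAsFactors = FALSE,
                          colClasses = c(label = "character"))
  nodes <- unique(long[, c("node", "label", "age")])
  out <- nodes[order(-nodes$age), ]
  for (v in unique(long$variable)) {
    sub <- long[long$variable == v, ]
    out[[v]] <- sub$value[match(out$node, sub$node)]
  }
  rownames(out) <- NULL
  structure(out, class = c("trajectory", "data.frame"))
}
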