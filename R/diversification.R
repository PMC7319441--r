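#' Construct a rate-shift event configuration
#'
#' An event configuration assigns every branch of a chronogram to exactly one
#' diversification process. Each process has an initial speciation rate
#' `lambda0`, an exponential change parameter `z` (per Myr; speciation at age
#' `t` is `lambda0 * exp(z * (start_age - t))`, with elapsed time measured
#' forward from the process start), and a constant extinction rate `mu0`.
#' One process is the root (background) process (`node = NA`, starting at the
#' root age); any other process starts at its shift node's age and governs
#' the branches of that node's subtree, unless overridden by a more recent
#' nested shift.
#'
#' @param tree a chronogram.
#' @param processes `data.frame` with columns `node` (node number; `NA` for
#'   the root process, exactly one row), `lambda0` (>= 0), `z`, `mu0` (>= 0).
#' @return an object of class `"event_configuration"`: list with `processes`
#'   (including `start_age`) and an `edges` table mapping each branch
#'   (parent, child, age interval) to its governing process.
#' @export
event_configuration <- function(tree, processes) {
  tree <- as_chronogram(tree)
  processes <- as.data.frame(processes)
  stopifnot(all(c("node", "lambda0", "z", "mu0") %in% names(processes)))
  if (any(processes$lambda0 < 0) || any(processes$mu0 < 0))
    stop_ccl("`lambda0` and `mu0` must be >= 0")
  if (sum(is.na(processes$node)) != 1L)
    stop_ccl("exactly one root process (node = NA) is required")
  nn <- length(tree$tip.label) + tree$Nnode
  shift_nodes <- processes$node[!is.na(processes$node)]
  if (any(shift_nodes < 1L | shift_nodes > nn))
    stop_ccl("shift node(s) not in tree: ",
             paste(setdiff(shift_nodes, seq_len(nn)), collapse = ", "))
  if (anyDuplicated(shift_nodes))
    stop_ccl("duplicate shift on node(s): ",
             paste(unique(shift_nodes[duplicated(shift_nodes)]), collapse = ", "))

  ages <- node_ages(tree)
  root <- length(tree$tip.label) + 1L
  processes$id <- seq_len(nrow(processes))
  processes$start_age <- ifelse(is.na(processes$node), ages[root],
                                ages[pmax(processes$node, 1L)])

  # governing process per node = most recent ancestral-or-self shift
  gov <- integer(nn)
  gov[root] <- processes$id[is.na(processes$node)]
  shift_of <- integer(nn)
  shift_of[shift_nodes] <- processes$id[!is.na(processes$node)]
  if (shift_of[root] > 0L) gov[root] <- shift_of[root]
  for (e in rev(ape::postorder(tree))) {       # preorder
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    gov[ch] <- if (shift_of[ch] > 0L) shift_of[ch] else gov[p]
  }
  edges <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                      parent_age = ages[tree$edge[, 1L]],
                      child_age = ages[tree$edge[, 2L]],
                      process = gov[tree$edge[, 1L]])
  structure(list(processes = processes[, c("id", "node", "start_age",
                                           "lambda0", "z", "mu0")],
                 edges = edges, root_age = ages[root]),
            class = "event_configuration")
}

#' @export
print.event_configuration <- function(x, ...) {
  cat(sprintf("Event configuration: %d process(es), %d branches\n",
              nrow(x$processes), nrow(x$edges)))
  print(x$processes, row.names = FALSE)
  invisible(x)
}

#' Speciation, extinction and net rate on a branch at a given age
#'
#' Evaluates the governing process of a branch at an age within the branch's
#' interval: `lambda(t) = lambda0 * exp(z * (start_age - t))`, constant
#' `mu = mu0`, and `r = lambda - mu`.
#'
#' @param config an [event_configuration()].
#' @param branch edge index (row of the configuration's `edges` table).
#' @param age age in Ma inside the branch's interval
#'   `[child age, parent age]`.
#' @return named numeric vector `c(lambda, mu, r)`.
#' @export
branch_rate_at <- function(config, branch, age) {
  stopifnot(inherits(config, "event_configuration"))
  e <- config$edges
  if (branch < 1L || branch > nrow(e)) stop_ccl("no such branch: ", branch)
  if (age < e$child_age[branch] || age > e$parent_age[branch])
    stop_ccl(sprintf("age %g outside branch interval [%g, %g]",
                     age, e$child_age[branch], e$parent_age[branch]))
  p <- config$processes[e$process[branch], ]
  if (age > p$start_age)
    stop_ccl(sprintf("age %g is older than the process start (%g Ma)",
                     age, p$start_age))
  lam <- p$lambda0 * exp(p$z * (p$start_age - age))
  c(lambda = lam, mu = p$mu0, r = lam - p$mu0)
}

#' Median net diversification rate through time
#'
#' For each grid age, every lineage alive at that age (see [lineages_at()])
#' gets a per-lineage net rate equal to the mean of `r = lambda - mu` over
#' the supplied event configurations; the series value is the median of
#' those per-lineage rates (midpoint median for even counts). This is the
#' rate-through-time summary of a posterior sample of rate-shift
#' configurations.
#'
#' @param tree a chronogram.
#' @param configs one [event_configuration()] or a list of them.
#' @param grid ages (Ma) within `[0, root age]`.
#' @return a `"rate_series"` data.frame with `age` and `rate`
#'   (events/lineage/Myr), sorted by decreasing age.
#' @export
rate_through_time <- function(tree, configs, grid) {
  tree <- as_chronogram(tree)
  if (inherits(configs, "event_configuration")) configs <- list(configs)
  if (length(configs) < 1L) stop_ccl("need at least one event configuration")
  if (length(grid) < 1L) stop_ccl("empty age grid")
  ra <- root_age(tree)
  if (any(grid < 0) || any(grid > ra + 1e-9))
    stop_ccl("grid age(s) outside [0, root age = ", format(ra), "]")
  grid <- sort(pmin(grid, ra), decreasing = TRUE)

  rate <- vapply(grid, function(t) {
    edges <- lineages_at(tree, t)
    per_config <- vapply(configs, function(cf) {
      p <- cf$processes[cf$edges$process[edges], ]
      p$lambda0 * exp(p$z * (p$start_age - t)) - p$mu0
    }, numeric(length(edges)))
    per_lineage <- if (length(edges) == 1L) mean(per_config) else
      rowMeans(matrix(per_config, nrow = length(edges)))
    stats::median(per_lineage)
  }, 0)
  structure(data.frame(age = grid, rate = rate),
            class = c("rate_series", "data.frame"))
}

#' Clade sampling fractions from a richness table
#'
#' For each named clade, the sampling fraction is the number of tree tips
#' assigned to the clade divided by the clade's described species richness.
#' The global sampling probability defaults to 1.0, the convention when the
#' clade table covers the complete richness of the group.
#'
#' @param tree a chronogram.
#' @param richness named numeric vector: described species per clade.
#' @param clade_map named list: tip labels per clade (names match
#'   `richness`).
#' @param global global sampling probability (default 1.0).
#' @return a data.frame (`clade`, `richness`, `tips`, `fraction`) with
#'   attribute `global`.
#' @export
sampling_fractions <- function(tree, richness, clade_map, global = 1.0) {
  tree <- as_chronogram(tree)
  clades <- names(richness)
  if (is.null(clades) || !all(clades %in% names(clade_map)))
    stop_ccl("`richness` and `clade_map` must share clade names")
  rows <- lapply(clades, function(cl) {
    tips <- intersect(clade_map[[cl]], tree$tip.label)
    if (length(tips) == 0L) stop_ccl("clade with zero sampled tips: ", cl)
    if (richness[[cl]] < length(tips))
      stop_ccl(sprintf("clade %s: richness %g < %d sampled tips",
                       cl, richness[[cl]], length(tips)))
    data.frame(clade = cl, richness = richness[[cl]], tips = length(tips),
               fraction = length(tips) / richness[[cl]])
  })
  out <- do.call(rbind, rows)
  attr(out, "global") <- global
  out
}

#' Read posterior event configurations (the "event data" dialect)
#'
#' Parses the de facto posterior event-data table written by rate-shift
#' MCMC samplers: comma- or tab-separated columns `generation`, `leftchild`,
#' `rightchild`, `abstime`, `lambdainit`, `lambdashift`, `muinit`. Each
#' generation becomes one [event_configuration()]: the event anchored at the
#' root (abstime 0) is the background process; every other event is a shift
#' at the most recent common ancestor of `leftchild` and `rightchild` (or at
#' the tip `leftchild` when `rightchild` is missing). `abstime` runs forward
#' from the root, so a process's start age is `root age - abstime`.
#'
#' @param path path to the event data file.
#' @param tree the chronogram the events refer to.
#' @return a list of [event_configuration()] objects, one per generation.
#' @export
read_event_data <- function(path, tree) {
  tree <- as_chronogram(tree)
  if (!file.exists(path)) stop_ccl("event data file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("generation", "leftchild", "abstime", "lambdainit",
            "lambdashift", "muinit")
  if (!all(need %in% names(x)))
    stop_ccl("event data needs columns: ", paste(need, collapse = ", "))
  if (!"rightchild" %in% names(x)) x$rightchild <- NA_character_
  ra <- root_age(tree)
  root <- length(tree$tip.label) + 1L

  node_of <- function(left, right) {
    if (is.na(right) || right == "" || right == "NA")
      return(match(left, tree$tip.label))
    ape::getMRCA(tree, c(left, right))
  }
  lapply(split(x, x$generation), function(g) {
    nodes <- mapply(node_of, g$leftchild, g$rightchild)
    if (anyNA(nodes)) stop_ccl("event data references unknown tip labels")
    procs <- data.frame(node = ifelse(nodes == root, NA_integer_,
                                      as.integer(nodes)),
                        lambda0 = g$lambdainit, z = g$lambdashift,
                        mu0 = g$muinit)
    cfg <- event_configuration(tree, procs)
    # honour the recorded event times where they differ from node ages
    cfg$processes$start_age <- ra - g$abstime
    cfg
  })
}

#' Write a rate series as tab-separated text
#' @param series a `"rate_series"` from [rate_through_time()].
#' @param path output path.
#' @export
write_rate_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
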