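#' Edit-cost scheme for graph edit distance
#'
#' One scenario of edit costs. Deleting and adding an element of the same class
#' (species or interaction) are priced jointly, so a single value covers both.
#' Ecologically, flipping a link reverses the direction of energy flow, which
#' is rare and is typically priced highest; adding/removing an interaction is
#' the cheapest edit because trophic links are the most temporally variable.
#'
#' @param flip nonnegative cost of reversing a link's direction.
#' @param node nonnegative cost of deleting or adding a species.
#' @param link nonnegative cost of deleting or adding an interaction.
#' @param scenario optional scenario id (1-49) when the scheme comes from the
#'   standard grid, see [scenario_grid()].
#' @return object of class `"cost_scheme"`.
#' @examples
#' cost_scheme(flip = 0.75, node = 0.5, link = 0.25)
#' @export
cost_scheme <- function(flip, node, link, scenario = NULL) {
  stopifnot(is.numeric(flip), is.numeric(node), is.numeric(link),
            flip >= 0, node >= 0, link >= 0)
  structure(list(flip = as.numeric(flip), node = as.numeric(node),
                 link = as.numeric(link),
                 scenario = if (is.null(scenario)) NA_integer_ else as.integer(scenario)),
            class = "cost_scheme")
}

#' @export
print.cost_scheme <- function(x, ...) {
  cat(sprintf("Edit costs%s: flip %g, species add/delete %g, interaction add/delete %g\n",
              if (is.na(x$scenario)) "" else sprintf(" (scenario %d)", x$scenario),
              x$flip, x$node, x$link))
  invisible(x)
}

# Literal transcription of the 49-scenario grid: scenario 1 prices every edit
# at 1; scenarios 2-25 cross flip 0.25 with species and interaction costs in
# {0, 0.25, 0.5, 0.75, 1} minus the all-free (node 0, link 0) cell; scenarios
# 26-49 repeat the cross with flip 0.75. Stored as data, not regenerated, so
# any grid irregularity would survive; a generator cross-checks it in tests.
.scenario_table <- data.frame(
  scenario = 1:49,
  flip = c(1, rep(0.25, 24), rep(0.75, 24)),
  node = c(1,
           0, 0, 0, 0,
           0.25, 0.25, 0.25, 0.25, 0.25,
           0.5, 0.5, 0.5, 0.5, 0.5,
           0.75, 0.75, 0.75, 0.75, 0.75,
           1, 1, 1, 1, 1,
           0, 0, 0, 0,
           0.25, 0.25, 0.25, 0.25, 0.25,
           0.5, 0.5, 0.5, 0.5, 0.5,
           0.75, 0.75, 0.75, 0.75, 0.75,
           1, 1, 1, 1, 1),
  link = c(1,
           0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1,
           0, 0.25, 0.5, 0.75, 1)
)

#' The standard grid of 49 edit-cost scenarios
#'
#' @return data.frame with columns `scenario`, `flip`, `node`, `link`; one row
#'   per scenario, ids 1-49.
#' @export
scenario_grid <- function() .scenario_table

# regeneration by formula, used only to cross-check the transcription
.scenario_grid_generated <- function() {
  rows <- list(data.frame(scenario = 1, flip = 1, node = 1, link = 1))
  id <- 1L
  for (flip in c(0.25, 0.75)) {
    for (node in seq(0, 1, by = 0.25)) {
      for (link in seq(0, 1, by = 0.25)) {
        if (node == 0 && link == 0) next
        id <- id + 1L
        rows[[length(rows) + 1L]] <- data.frame(scenario = id, flip = flip,
                                                node = node, link = link)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cost scheme for a grid scenario
#'
#' @param id scenario id, 1-49.
#' @return the corresponding [cost_scheme].
#' @export
scenario_costs <- function(id) {
  g <- scenario_grid()
  i <- match(as.integer(id), g$scenario)
  if (is.na(i)) stop("unknown scenario id: ", id)
  cost_scheme(g$flip[i], g$node[i], g$link[i], scenario = g$scenario[i])
}
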