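#' Read a reaction-network model file
#'
#' The model format is a YAML key--value document with two top-level keys:
#' `species` (a list of records with `id`, optional `boundary: true` and
#' `conc` for boundary species) and `reactions` (records with `id`,
#' `reactants` and `products` maps of stoichiometric coefficients, `k_fwd`
#' and `k_rev`). All network invariants are checked on load, and a file
#' written by [write_network()] reads back to an identical network.
#'
#' @param path path of a model file.
#' @return a [reaction_network()].
#' @export
read_network <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("model file '", path, "' is not valid YAML: ", conditionMessage(e)))
  for (key in c("species", "reactions"))
    if (is.null(doc[[key]]))
      stop("model file is missing the top-level key '", key, "'")
  species <- character()
  boundary <- numeric()
  for (rec in doc$species) {
    if (is.null(rec$id)) stop("species record without an 'id' field")
    if (isTRUE(rec$boundary)) {
      if (is.null(rec$conc))
        stop("boundary species '", rec$id, "' has no fixed concentration ('conc')")
      boundary[rec$id] <- as.numeric(rec$conc)
    } else {
      species <- c(species, rec$id)
    }
  }
  reactions <- lapply(doc$reactions, function(rec) {
    for (fld in c("id", "reactants", "products", "k_fwd", "k_rev"))
      if (is.null(rec[[fld]]))
        stop("reaction record ",
             if (!is.null(rec$id)) paste0("'", rec$id, "' ") else "",
             "is missing field '", fld, "'")
    list(id = rec$id,
         reactants = unlist(rec$reactants),
         products = unlist(rec$products),
         k_fwd = as.numeric(rec$k_fwd),
         k_rev = as.numeric(rec$k_rev))
  })
  reaction_network(species, boundary, reactions)
}

# full-precision numeric literal that yaml parses back exactly
.num_lit <- function(x) {
  s <- sprintf("%.17g", x)
  if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
  s
}

#' Write a reaction-network model file
#'
#' Serializes a network to the YAML model format of [read_network()] with
#' full double precision, so that read -> write -> read round-trips are
#' bit-exact.
#'
#' @param network a [reaction_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("species:")
  for (sp in network$species_names) w("  - id: ", sp)
  for (sp in names(network$boundary_conc)) {
    w("  - id: ", sp)
    w("    boundary: true")
    w("    conc: ", .num_lit(network$boundary_conc[[sp]]))
  }
  w("reactions:")
  for (r in network$reactions) {
    w("  - id: ", r$id)
    w("    reactants: {",
      paste(sprintf("%s: %d", names(r$reactants), as.integer(r$reactants)),
            collapse = ", "), "}")
    w("    products: {",
      paste(sprintf("%s: %d", names(r$products), as.integer(r$products)),
            collapse = ", "), "}")
    w("    k_fwd: ", .num_lit(r$k_fwd))
    w("    k_rev: ", .num_lit(r$k_rev))
  }
  invisible(path)
}

#' Read a concentration trajectory table
#'
#' Expects a tab- or comma-delimited table whose first column is `time` and
#' whose remaining columns are species concentrations.
#'
#' @param path path of the delimited table.
#' @return a tibble with `time` plus one column per species; attribute
#'   `provenance` is `"loaded"`.
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (names(df)[1] != "time")
    stop("trajectory table must have 'time' as its first column")
  if (any(diff(df$time) <= 0)) stop("non-monotone time column in trajectory table")
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- "loaded"
  out
}

#' Write a concentration trajectory table
#'
#' @param traj trajectory tibble (`time` column plus species columns).
#' @param path output path; written tab-delimited at full double precision.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  .validate_trajectory(traj)
  fmt <- vapply(traj, function(col) sprintf("%.17g", col), character(nrow(traj)))
  if (nrow(traj) == 1) fmt <- matrix(fmt, nrow = 1, dimnames = list(NULL, names(traj)))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = names(traj))
  invisible(path)
}
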