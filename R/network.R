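#' Enzyme registry for the tryptophan indole pathway
#'
#' The 14 enzyme families of the microbial tryptophan catabolism network.
#' \code{HdhD} (D-2-hydroxyacid dehydrogenase) shares its partial EC number
#' with \code{fldH} and acts as an indole-3-lactate dehydrogenase; by default
#' its homologs are counted under the \code{fldH} family (see
#' \code{\link{enzymes_present}}). The phenyllactate dehydratase cluster is
#' modeled as three families \code{fldA}, \code{fldBC}, \code{fldI}, with the
#' alpha/beta subunits \code{fldBC} treated as one unit.
#'
#' @return A data.frame with columns \code{abbrev}, \code{full_name},
#'   \code{ec_number}, \code{role_note}.
#' @export
enzyme_registry <- function() {
  reg <- data.frame(
    abbrev = c("ArAT", "TDC", "TMO", "amiE", "fldH", "LDH", "HdhD",
               "fldA", "fldBC", "fldI", "acdA", "ALD", "IPD", "PPD"),
    full_name = c(
      "aromatic amino acid aminotransferase",
      "tryptophan decarboxylase",
      "tryptophan 2-monooxygenase",
      "amidase",
      "indolelactate dehydrogenase",
      "lactate dehydrogenase",
      "D-2-hydroxyacid dehydrogenase",
      "cinnamoyl-CoA:phenyllactate CoA-transferase",
      "phenyllactoyl-CoA dehydratase alpha/beta",
      "R-phenyllactate dehydratase activator",
      "phenylacrylate reductase",
      "aldehyde dehydrogenase",
      "indolepyruvate decarboxylase",
      "phenylpyruvate decarboxylase"),
    ec_number = c("2.6.1.-", "4.1.1.28", "1.13.12.3", "3.5.1.4", "1.1.1.-",
                  "1.1.1.-", "1.1.1.-", "2.8.3.17", "4.2.1.-", "1.-.-.-",
                  "1.3.1.-", "1.2.1.3", "4.1.1.74", "4.1.1.43"),
    role_note = c(
      "first step: Trp -> IPYA",
      "first step: Trp -> TA",
      "first step: Trp -> IAM",
      "IAM -> IAA",
      "IPYA -> ILA",
      "IPYA -> ILA (alternative)",
      "counted as fldH-equivalent ILA dehydrogenase",
      "ILA -> IA cluster member",
      "ILA -> IA cluster member (two subunits, one family)",
      "ILA -> IA cluster member",
      "IA -> IPA",
      "IAAld -> IAA",
      "IPYA -> IAAld",
      "IPYA -> IAAld (alternative)"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$abbrev),
            all(grepl("^[0-9]+(\\.([0-9]+|-)){3}$", reg$ec_number)))
  reg
}

#' Display names of the network metabolites
#' @return Named character vector mapping metabolite id to full name.
#' @export
metabolite_names <- function() {
  c(Trp   = "tryptophan",
    IPYA  = "indole-3-pyruvic acid",
    ILA   = "indole-3-lactic acid",
    IA    = "3-indoleacrylic acid",
    IPA   = "indole-3-propionic acid",
    IAM   = "indole-3-acetamide",
    TA    = "tryptamine",
    IAAld = "indole-3-acetaldehyde",
    IAA   = "indole-3-acetic acid",
    IAld  = "3-indolealdehyde")
}

new_requirement <- function(alternatives) {
  stopifnot(is.list(alternatives), length(alternatives) >= 1)
  alternatives <- lapply(alternatives, function(a) sort(as.character(a)))
  structure(list(alternatives = alternatives), class = "trp_requirement")
}

# UNKNOWN requirement: no alternatives can ever be satisfied
unknown_requirement <- function() {
  structure(list(alternatives = list()), class = "trp_requirement")
}

#' Test whether an enzyme set satisfies a reaction requirement
#'
#' A requirement is a disjunction of conjunctions of enzyme families: it is
#' satisfied iff at least one alternative is fully contained in the
#' available-enzyme set. The unknown requirement (empty disjunction) is never
#' satisfied. Satisfaction is monotone in the enzyme set.
#'
#' @param req A requirement object (see \code{\link{build_default_network}}).
#' @param present Character vector of enzyme family abbreviations.
#' @return Logical scalar.
#' @export
satisfies <- function(req, present) {
  stopifnot(inherits(req, "trp_requirement"))
  if (length(req$alternatives) == 0L) return(FALSE)
  any(vapply(req$alternatives, function(a) all(a %in% present), logical(1)))
}

#' Build the default tryptophan metabolic network
#'
#' The microbial branch of tryptophan catabolism: 10 metabolites and 10
#' directed reactions rooted at tryptophan. Each edge carries the enzyme
#' requirement for the reaction; the terminal IAA -> IAld step has an unknown
#' enzyme and is never satisfiable, so IAld is excluded from the predictable
#' set.
#'
#' @return An object of class \code{trp_network} with elements
#'   \code{metabolites}, \code{edges} (data.frame \code{substrate},
#'   \code{product} plus a parallel list of requirements), \code{root},
#'   \code{predictable}, \code{registry}.
#' @examples
#' net <- build_default_network()
#' net$predictable
#' satisfies(net$requirements[[4]], "LDH")
#' @export
build_default_network <- function() {
  edges <- list(
    list("Trp",   "IPYA",  list("ArAT")),
    list("Trp",   "TA",    list("TDC")),
    list("Trp",   "IAM",   list("TMO")),
    list("IPYA",  "ILA",   list("fldH", "LDH")),
    list("ILA",   "IA",    list(c("fldA", "fldBC", "fldI"))),
    list("IA",    "IPA",   list("acdA")),
    list("IPYA",  "IAAld", list("IPD", "PPD")),
    list("IAAld", "IAA",   list("ALD")),
    list("IAM",   "IAA",   list("amiE")),
    list("IAA",   "IAld",  NULL)  # producing enzyme unknown
  )
  df <- data.frame(
    substrate = vapply(edges, `[[`, "", 1),
    product   = vapply(edges, `[[`, "", 2),
    stringsAsFactors = FALSE)
  reqs <- lapply(edges, function(e)
    if (is.null(e[[3]])) unknown_requirement() else new_requirement(e[[3]]))
  build_network(names(metabolite_names()), df, reqs)
}

# Internal constructor + validator shared by the default builder and the
# JSON loader.
build_network <- function(metabolites, edge_df, requirements,
                          registry = enzyme_registry()) {
  stopifnot(nrow(edge_df) == length(requirements))
  bad <- edge_df$substrate == edge_df$product
  if (any(bad))
    stop("self-loop edge not allowed: ", edge_df$substrate[which(bad)[1]],
         " -> ", edge_df$product[which(bad)[1]])
  missing_node <- setdiff(c(edge_df$substrate, edge_df$product), metabolites)
  if (length(missing_node))
    stop("edge references unknown metabolite: ",
         paste(missing_node, collapse = ", "))
  for (k in seq_along(requirements)) {
    enz <- unlist(requirements[[k]]$alternatives)
    unknown <- setdiff(enz, registry$abbrev)
    if (length(unknown))
      stop("edge ", edge_df$substrate[k], " -> ", edge_df$product[k],
           " references enzyme absent from registry: ",
           paste(unknown, collapse = ", "))
  }
  check_acyclic(metabolites, edge_df)
  root <- "Trp"
  reach_all <- reachable(root, edge_df, ignore_requirements = TRUE)
  unreachable <- setdiff(metabolites, c(root, reach_all))
  if (length(unreachable))
    stop("metabolites unreachable from ", root, ": ",
         paste(unreachable, collapse = ", "))
  # predictable: every edge on some root-path has a known (non-empty)
  # requirement
  known <- vapply(requirements, function(r) length(r$alternatives) > 0,
                  logical(1))
  predictable <- intersect(metabolites,
                           reachable(root, edge_df[known, , drop = FALSE],
                                     ignore_requirements = TRUE))
  structure(list(metabolites = metabolites, edges = edge_df,
                 requirements = requirements, root = root,
                 predictable = predictable, registry = registry),
            class = "trp_network")
}

check_acyclic <- function(metabolites, edge_df) {
  # Kahn's algorithm; report a cycle if topological sort stalls
  nodes <- metabolites
  edges <- edge_df
  repeat {
    if (nrow(edges) == 0) return(invisible(TRUE))
    sinks_ok <- setdiff(nodes, edges$product)  # nodes with in-degree 0
    drop <- edges$substrate %in% sinks_ok
    if (!any(drop)) {
      cyc <- unique(c(edges$substrate, edges$product))
      stop("cycle detected among metabolites: ", paste(cyc, collapse = ", "))
    }
    edges <- edges[!drop, , drop = FALSE]
    nodes <- setdiff(nodes, sinks_ok)
  }
}

# BFS over the edge list from `root`; returns reached nodes (excluding root).
reachable <- function(root, edge_df, ignore_requirements = FALSE,
                      requirements = NULL, present = NULL) {
  open_edges <- if (ignore_requirements) rep(TRUE, nrow(edge_df)) else
    vapply(requirements, satisfies, logical(1), present = present)
  seen <- root
  frontier <- root
  while (length(frontier)) {
    nxt <- edge_df$product[open_edges & edge_df$substrate %in% frontier]
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  setdiff(seen, root)
}

#' @export
print.trp_network <- function(x, ...) {
  cat("Tryptophan metabolic network:", length(x$metabolites), "metabolites,",
      nrow(x$edges), "edges (",
      sum(vapply(x$requirements, function(r) length(r$alternatives) > 0,
                 logical(1))), "with known requirements)\n")
  cat("Predictable:", paste(x$predictable, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a metabolic network as JSON
#'
#' The document has keys \code{metabolites} (array of ids) and \code{edges},
#' each edge an object \code{{substrate, product, alternatives}} where
#' \code{alternatives} is an array of arrays of enzyme abbreviations (empty
#' array = unknown requirement). Validation mirrors
#' \code{\link{build_default_network}}: self-loops, unknown metabolites or
#' enzymes, and cycles are rejected with messages naming the offender.
#'
#' @param path File path of the JSON document.
#' @param network For \code{save_network}, a \code{trp_network}.
#' @return \code{load_network} returns a \code{trp_network};
#'   \code{save_network} returns \code{path} invisibly.
#' @export
load_network <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$edges))
    stop("network document must have 'metabolites' and 'edges'")
  metabolites <- vapply(doc$metabolites, as.character, "")
  edge_df <- data.frame(
    substrate = vapply(doc$edges, function(e) as.character(e$substrate), ""),
    product   = vapply(doc$edges, function(e) as.character(e$product), ""),
    stringsAsFactors = FALSE)
  reqs <- lapply(doc$edges, function(e) {
    alts <- lapply(e$alternatives, function(a)
      vapply(as.list(a), as.character, ""))
    if (length(alts) == 0) unknown_requirement() else new_requirement(alts)
  })
  build_network(metabolites, edge_df, reqs)
}

#' @rdname load_network
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "trp_network"))
  doc <- list(
    metabolites = network$metabolites,
    edges = lapply(seq_len(nrow(network$edges)), function(k) list(
      substrate = network$edges$substrate[k],
      product = network$edges$product[k],
      # I() keeps each alternative an array even when it has one member
      alternatives = lapply(network$requirements[[k]]$alternatives, I))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
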