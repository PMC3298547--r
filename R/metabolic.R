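#' Read a reaction table
#'
#' TSV with columns `reaction_id`, `enzyme_id` (EC-number-like string),
#' `educts` and `products` (semicolon-joined substrate ids) and `reversible`
#' (0/1). Every record must have at least one enzyme, educt and product.
#'
#' @param path input TSV path.
#' @return a `pkn_reactions` data frame with list columns `educts`,
#'   `products`.
#' @export
read_reaction_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("reaction_id", "enzyme_id", "educts", "products", "reversible")
  if (!all(need %in% names(d)))
    stop("reaction table needs columns: ", paste(need, collapse = ", "))
  pkn_reactions(d$reaction_id, d$enzyme_id,
                strsplit(d$educts, ";", fixed = TRUE),
                strsplit(d$products, ";", fixed = TRUE),
                as.integer(d$reversible) == 1L)
}

#' @rdname read_reaction_table
#' @param reaction_id,enzyme_id character vectors.
#' @param educts,products lists of character vectors of substrate ids.
#' @param reversible logical vector.
#' @export
pkn_reactions <- function(reaction_id, enzyme_id, educts, products,
                          reversible) {
  educts <- lapply(educts, function(x) unique(as.character(x)))
  products <- lapply(products, function(x) unique(as.character(x)))
  ok <- lengths(educts) >= 1L & lengths(products) >= 1L &
    nzchar(enzyme_id) & nzchar(reaction_id)
  if (!all(ok))
    stop("every reaction record needs an enzyme, >=1 educt and >=1 product")
  d <- data.frame(reaction_id = as.character(reaction_id),
                  enzyme_id = as.character(enzyme_id),
                  reversible = as.logical(reversible),
                  stringsAsFactors = FALSE)
  d$educts <- educts
  d$products <- products
  class(d) <- c("pkn_reactions", "data.frame")
  d
}

#' Write a reaction table
#' @param rt a `pkn_reactions`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(rt, path) {
  d <- data.frame(reaction_id = rt$reaction_id,
                  enzyme_id = rt$enzyme_id,
                  educts = vapply(rt$educts, paste, "", collapse = ";"),
                  products = vapply(rt$products, paste, "", collapse = ";"),
                  reversible = as.integer(rt$reversible),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count reactions each substrate participates in
#'
#' Distinct reaction records in which the substrate appears as educt or
#' product; a substrate occurring on both sides of one reaction counts once.
#' Counts are taken before any currency filtering.
#'
#' @param rt a `pkn_reactions`.
#' @return named integer vector, one entry per substrate.
#' @export
substrate_reaction_counts <- function(rt) {
  per_rxn <- Map(function(e, p) unique(c(e, p)), rt$educts, rt$products)
  tab <- table(unlist(per_rxn, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the enzyme-centered metabolic network
#'
#' Vertices are enzyme activities (one vertex per enzyme id, however many
#' reactions it catalyses). A directed edge E1 -> E2 is drawn when some
#' shared substrate is the product of a reaction of E1 and the educt of a
#' reaction of E2. Ubiquitous "currency" substrates (e.g. ATP, water) taking
#' part in more than `currency_threshold` reactions are discarded before
#' edge construction. A reversible reaction contributes both orientations
#' (educts and products swapped). Self-edges are excluded.
#'
#' @param rt a `pkn_reactions`.
#' @param currency_threshold substrates in more than this many reactions are
#'   dropped (default 100).
#' @return a `pkn_network` over all enzyme ids.
#' @export
build_enzyme_network <- function(rt, currency_threshold = 100) {
  stopifnot(currency_threshold >= 1)
  counts <- substrate_reaction_counts(rt)
  currency <- names(counts)[counts > currency_threshold]
  n <- nrow(rt)
  # directed educt/product sets after expanding reversible reactions
  consumes <- produces <- vector("list", 2L * n)
  enz <- character(2L * n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    enz[m] <- rt$enzyme_id[i]
    consumes[[m]] <- setdiff(rt$educts[[i]], currency)
    produces[[m]] <- setdiff(rt$products[[i]], currency)
    if (rt$reversible[i]) {
      m <- m + 1L
      enz[m] <- rt$enzyme_id[i]
      consumes[[m]] <- setdiff(rt$products[[i]], currency)
      produces[[m]] <- setdiff(rt$educts[[i]], currency)
    }
  }
  length(enz) <- length(consumes) <- length(produces) <- m
  prod_tab <- data.frame(
    substrate = unlist(produces, use.names = FALSE),
    enzyme = rep(enz, lengths(produces)), stringsAsFactors = FALSE)
  cons_tab <- data.frame(
    substrate = unlist(consumes, use.names = FALSE),
    enzyme = rep(enz, lengths(consumes)), stringsAsFactors = FALSE)
  joined <- merge(unique(prod_tab), unique(cons_tab), by = "substrate",
                  suffixes = c("_tail", "_head"))
  ed <- unique(data.frame(from = joined$enzyme_tail, to = joined$enzyme_head,
                          label = rep("substrate", nrow(joined)),
                          stringsAsFactors = FALSE))
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  pkn_network(unique(rt$enzyme_id), ed, name = "metabolic")
}
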