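#' Type-resolved hub set of a hub table
#'
#' Members are `(node, type)` pairs encoded as `"node|type"`, so a node
#' that stays a hub but changes type counts toward the variant structure
#' when two conditions are compared.
#'
#' @param ht a [hub_table()].
#' @return Character vector of `"node|type"` members.
#' @export
hub_set <- function(ht) {
  sel <- ht$is_hub
  paste(ht$node[sel], ht$hub_type[sel], sep = "|")
}

#' Homogeneity of two hub sets
#'
#' `Gamma = 2 n(A intersect B) / (n(A) + n(B))`: the stable fraction of
#' the connective core shared by two conditions. 1 for identical sets,
#' 0 for disjoint ones.
#'
#' @param A,B hub sets (character vectors, typically from [hub_set()]);
#'   at least one must be nonempty.
#' @return Gamma in `[0, 1]`.
#' @export
homogeneity <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) + length(B) == 0)
    stop("both hub sets are empty: homogeneity undefined")
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

#' Heterogeneity of two hub sets
#'
#' `Lambda = (n(A') + n(B')) / (n(A) + n(B))` with the complements taken
#' within the union of the two cores (`A' = A \ B`, `B' = B \ A`): the
#' variable fraction of the connective core. Complements to
#' [homogeneity()]: `Gamma + Lambda = 1`.
#'
#' @inheritParams homogeneity
#' @return Lambda in `[0, 1]`.
#' @export
heterogeneity <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) + length(B) == 0)
    stop("both hub sets are empty: heterogeneity undefined")
  (length(setdiff(A, B)) + length(setdiff(B, A))) / (length(A) + length(B))
}

#' Hub-transition accounting between two conditions
#'
#' Every node that is a hub in at least one condition contributes one
#' transition `type_before -> type_after`, where `NH` denotes not being
#' a hub. Fractions are normalized over all contributing nodes and sum
#' to 1; transitions `HD->HD`, `HC->HC`, `HN->HN` form the invariant
#' structure, everything else the variant structure. The summary also
#' carries the homogeneity and heterogeneity of the type-resolved hub
#' sets.
#'
#' @param before,after [hub_table()]s over the same channel set.
#' @return An object of class `core_transition`: list with
#'   `transitions` (data frame: `transition`, `count`, `fraction`,
#'   `invariant`), `gamma`, `lambda`, `condition_pair`.
#' @export
transition_table <- function(before, after) {
  if (!setequal(before$node, after$node))
    stop("hub tables cover different channel sets")
  tb <- stats::setNames(ifelse(before$is_hub, before$hub_type, "NH"), before$node)
  ta <- stats::setNames(ifelse(after$is_hub, after$hub_type, "NH"), after$node)
  ta <- ta[names(tb)]
  involved <- tb != "NH" | ta != "NH"
  if (!any(involved)) stop("no hubs in either condition")
  trans <- paste(tb[involved], ta[involved], sep = "->")
  lev <- as.vector(outer(c("HD", "HC", "HN", "NH"),
                         c("HD", "HC", "HN", "NH"), paste, sep = "->"))
  lev <- setdiff(lev, "NH->NH")
  tab <- table(factor(trans, levels = lev))
  df <- data.frame(transition = names(tab), count = as.integer(tab),
                   fraction = as.numeric(tab) / sum(tab), row.names = NULL)
  df$invariant <- df$transition %in% c("HD->HD", "HC->HC", "HN->HN")
  A <- hub_set(before); B <- hub_set(after)
  structure(list(transitions = df,
                 gamma = homogeneity(A, B),
                 lambda = heterogeneity(A, B),
                 condition_pair = c(before = before_tag(before),
                                    after = before_tag(after))),
            class = "core_transition")
}

before_tag <- function(ht) {
  tag <- attr(ht, "condition")
  if (is.null(tag)) "" else tag
}

#' @export
print.core_transition <- function(x, ...) {
  cat(sprintf("<core_transition> gamma = %.3f, lambda = %.3f\n",
              x$gamma, x$lambda))
  shown <- x$transitions[x$transitions$count > 0, ]
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  %-8s %5.1f%%%s\n", shown$transition[i],
                100 * shown$fraction[i],
                if (shown$invariant[i]) "  (invariant)" else ""))
  invisible(x)
}

#' Write a core transition as delimited text
#' @param ct a `core_transition`.
#' @param path file path.
#' @export
write_transition <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gamma=%.10g lambda=%.10g", ct$gamma, ct$lambda), con)
  write.table(ct$transitions, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
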