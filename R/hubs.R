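#' Output and input degree of a node
#'
#' The output degree (OD) is the sum of the node's outgoing NTE weights,
#' the input degree (ID) the sum of its incoming weights, following the
#' rows = receivers / columns = senders orientation.
#'
#' @param cm a `connectivity_matrix`.
#' @param node a channel label.
#' @return Named numeric vector `c(OD = ..., ID = ...)`.
#' @export
degrees <- function(cm, node) {
  i <- match(node, cm$channel_labels)
  if (is.na(i)) stop("unknown node label: ", node)
  c(OD = sum(cm$weights[, i]), ID = sum(cm$weights[i, ]))
}

#' Classify a hub as divergent, convergent or neutral
#'
#' Divergent (`HD`) when the output degree exceeds the input degree by
#' more than the threshold fraction (`OD > ID * (1 + threshold)`),
#' convergent (`HC`) for the mirror condition, neutral (`HN`) otherwise.
#' The comparison is multiplicative, hence scale-invariant, as the
#' unit-free NTE ratios require; boundary equality is neutral, and an
#' isolated node (`OD = ID = 0`) is neutral.
#'
#' @param OD,ID nonnegative output and input degrees.
#' @param threshold imbalance fraction (default 0.10).
#' @return One of `"HD"`, `"HC"`, `"HN"`.
#' @export
classify_hub <- function(OD, ID, threshold = 0.10) {
  stopifnot(OD >= 0, ID >= 0, threshold > 0)
  if (OD > ID * (1 + threshold)) "HD"
  else if (ID > OD * (1 + threshold)) "HC"
  else "HN"
}

#' Per-node hub table with net entropy and typing
#'
#' Combines a hub flagging (from [identify_hubs()]) with the net
#' normalized transfer entropy `K = OD - ID` and the hub-type
#' classification. `K`, `OD` and `ID` are reported for every node as
#' diagnostics; `hub_type` is assigned only to flagged hubs (`"none"`
#' otherwise).
#'
#' @param cm a `connectivity_matrix`.
#' @param hubs data frame from [identify_hubs()] (columns `node`,
#'   `is_hub`), or a character vector of hub labels.
#' @param threshold imbalance fraction, see [classify_hub()].
#' @return A data frame of class `hub_table` with columns `node`,
#'   `is_hub`, `OD`, `ID`, `K`, `hub_type`.
#' @export
hub_table <- function(cm, hubs, threshold = 0.10) {
  labels <- cm$channel_labels
  if (is.data.frame(hubs)) {
    flags <- stats::setNames(hubs$is_hub, hubs$node)[labels]
    flags[is.na(flags)] <- FALSE
  } else {
    flags <- labels %in% hubs
  }
  od <- colSums(cm$weights)
  id <- rowSums(cm$weights)
  type <- ifelse(flags,
                 mapply(classify_hub, od, id,
                        MoreArgs = list(threshold = threshold)),
                 "none")
  structure(data.frame(node = labels, is_hub = unname(flags),
                       OD = unname(od), ID = unname(id),
                       K = unname(od - id), hub_type = unname(type),
                       row.names = NULL),
            class = c("hub_table", "data.frame"))
}

#' Connective-core composition
#'
#' Fractions of divergent, convergent and neutral hubs among all flagged
#' hubs; the fractions sum to 1.
#'
#' @param ht a [hub_table()].
#' @return Named numeric vector `c(HD = , HC = , HN = )`.
#' @export
core_composition <- function(ht) {
  types <- ht$hub_type[ht$is_hub]
  if (length(types) == 0) stop("no hubs flagged: composition undefined")
  tab <- table(factor(types, levels = c("HD", "HC", "HN")))
  stats::setNames(as.numeric(tab) / length(types), names(tab))
}

#' Mean net entropy of a hub type
#'
#' Arithmetic mean of `K = OD - ID` over flagged hubs of the requested
#' type: positive for divergent hubs, negative for convergent hubs (by
#' construction of the classification). When a recording has no hub of
#' the requested type, `NA` is returned with attribute `absent = TRUE`,
#' so group summaries can condition on type presence.
#'
#' @param ht a [hub_table()].
#' @param hub_type one of `"HD"`, `"HC"`, `"HN"`.
#' @return Mean `K`, or `NA` (attribute `absent`) if no such hub exists.
#' @export
mean_net_entropy <- function(ht, hub_type = c("HD", "HC", "HN")) {
  hub_type <- match.arg(hub_type)
  k <- ht$K[ht$is_hub & ht$hub_type == hub_type]
  if (length(k) == 0) return(structure(NA_real_, absent = TRUE))
  mean(k)
}

#' Write / read a hub table as delimited text
#' @param ht a [hub_table()].
#' @param path file path.
#' @return `read_hub_table` returns a `hub_table`.
#' @export
write_hub_table <- function(ht, path) {
  write.table(ht, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hub_table
#' @export
read_hub_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "logical", "numeric",
                                  "numeric", "numeric", "character"))
  structure(df, class = c("hub_table", "data.frame"))
}
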