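# Parsing of model tables in the Netflux dialect: a nodes sheet
# (id, ymax, tau, y0, category) and a reactions sheet (rule, w, n, EC50).
# Rule strings look like "!A & B => C"; an empty left-hand side ("=> C")
# denotes an input reaction whose drive equals its weight.

# Split one rule string into operands / inhibition flags / target.
parseRule <- function(rule) {
  if (length(rule) != 1L || !is.character(rule) || !grepl("=>", rule, fixed = TRUE))
    stop("malformed rule string (expected 'operands => target'): ",
         deparse(rule), call. = FALSE)
  halves <- strsplit(rule, "=>", fixed = TRUE)[[1]]
  if (length(halves) > 2L)
    stop("malformed rule string (multiple '=>'): ", rule, call. = FALSE)
  target <- trimws(if (length(halves) == 2L) halves[2] else "")
  if (!nzchar(target) || grepl("[!&[:space:]]", target))
    stop("malformed rule string (bad target): ", rule, call. = FALSE)
  lhs <- trimws(halves[1])
  if (!nzchar(lhs))
    return(list(operands = character(), inhib = logical(), target = target))
  toks <- trimws(strsplit(lhs, "&", fixed = TRUE)[[1]])
  nAmp <- lengths(regmatches(lhs, gregexpr("&", lhs, fixed = TRUE)))
  if (length(toks) != nAmp + 1L || any(!nzchar(toks)))
    stop("malformed rule string (empty operand): ", rule, call. = FALSE)
  inhib <- startsWith(toks, "!")
  ops <- trimws(sub("^!", "", toks))
  if (any(!nzchar(ops)) || any(grepl("[!&[:space:]]", ops)))
    stop("malformed rule string (bad operand): ", rule, call. = FALSE)
  list(operands = ops, inhib = inhib, target = target)
}

# Category-driven time-constant defaults, in t/tau units: intracellular
# signaling equilibrates fast (0.005), gene-expression outputs slower
# (0.02), and the cell-size output relaxes on the growth time scale (1).
defaultTau <- function(category) {
  unname(c(input = 0.005, intermediate = 0.005,
           `gene-output` = 0.02, `growth-output` = 1)[category])
}

#' Parse Netflux-dialect model tables into a NetworkModel
#'
#' Reads a nodes table and a reactions table (data.frames or CSV file
#' paths) and returns a validated \linkS4class{NetworkModel}.  Nodes
#' require a column \code{id}; \code{ymax} (default 1), \code{y0}
#' (default 0), \code{category} (default "intermediate") and \code{tau}
#' are optional -- a missing or NA \code{tau} falls back to the
#' category-driven default (0.005 for inputs/intermediates, 0.02 for
#' gene outputs, 1 for growth outputs, all in t/tau units).  Reactions
#' require \code{rule}, \code{w}, \code{n}, \code{EC50}; an optional
#' \code{id} column names reactions (defaults to the rule string).
#'
#' Every node referenced by a rule must be declared; unknown references
#' and duplicated ids are rejected with the offending row identified.
#' Missing \code{n}/\code{EC50} entries are an error rather than silently
#' defaulted.
#'
#' @param nodesTable data.frame or path to a CSV file.
#' @param reactionsTable data.frame or path to a CSV file.
#' @return a \linkS4class{NetworkModel}.
#' @examples
#' nd <- data.frame(id = c("A", "B", "C"), y0 = 0, category = "intermediate")
#' rx <- data.frame(rule = c("A => B", "!B => C"), w = 1, n = 2, EC50 = 0.5)
#' parseModelTables(nd, rx)
#' @export
parseModelTables <- function(nodesTable, reactionsTable) {
  readTab <- function(x) {
    if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else
      as.data.frame(x, stringsAsFactors = FALSE)
  }
  nd <- readTab(nodesTable)
  rx <- readTab(reactionsTable)
  if (!"id" %in% names(nd)) stop("nodes table must contain an 'id' column")
  nd$id <- as.character(nd$id)
  if (anyDuplicated(nd$id))
    stop("duplicate node id: ",
         paste(unique(nd$id[duplicated(nd$id)]), collapse = ", "))
  if (is.null(nd$ymax)) nd$ymax <- 1
  if (is.null(nd$y0)) nd$y0 <- 0
  if (is.null(nd$category)) nd$category <- "intermediate"
  bad <- setdiff(unique(nd$category),
                 c("input", "intermediate", "gene-output", "growth-output"))
  if (length(bad)) stop("unknown node category: ", paste(bad, collapse = ", "))
  if (is.null(nd$tau)) nd$tau <- NA_real_
  nd$tau <- ifelse(is.na(nd$tau), defaultTau(nd$category), nd$tau)
  nd <- nd[c("id", "ymax", "tau", "y0", "category")]

  need <- c("rule", "w", "n", "EC50")
  miss <- setdiff(need, names(rx))
  if (length(miss))
    stop("reactions table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(rx$n) || anyNA(rx$EC50))
    stop("reactions table has missing n/EC50 in row(s): ",
         paste(which(is.na(rx$n) | is.na(rx$EC50)), collapse = ", "))
  if (is.null(rx$id)) rx$id <- make.unique(as.character(rx$rule))
  rx$id <- as.character(rx$id)

  ops <- vector("list", nrow(rx))
  rx$target <- NA_character_
  for (i in seq_len(nrow(rx))) {
    p <- tryCatch(parseRule(rx$rule[i]), error = function(e)
      stop("reactions row ", i, ": ", conditionMessage(e), call. = FALSE))
    unknown <- setdiff(c(p$operands, p$target), nd$id)
    if (length(unknown))
      stop("reactions row ", i, " references undeclared node(s): ",
           paste(unknown, collapse = ", "))
    rx$target[i] <- p$target
    ops[[i]] <- list(idx = match(p$operands, nd$id), inhib = p$inhib,
                     targetIdx = match(p$target, nd$id))
  }
  rx <- rx[c("id", "rule", "target", "w", "n", "EC50")]
  new("NetworkModel", nodes = nd, reactions = rx, ops = ops)
}

#' Export a trajectory as a tidy table
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param file optional CSV path; when given the table is also written.
#' @return a data.frame with columns \code{time}, \code{node},
#'   \code{activity} (long format).
#' @export
trajectoryToTidy <- function(traj, file = NULL) {
  a <- activities(traj)
  out <- data.frame(
    time = rep(trajTimes(traj), times = ncol(a)),
    node = rep(colnames(a), each = nrow(a)),
    activity = as.vector(a))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
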