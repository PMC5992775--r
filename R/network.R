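# Boolean network models: construction, parsing, serialization, wild-type
# augmentation, rate augmentation, and random generation.
#
# A network holds one update rule per variable.  Each rule stores its ordered
# input set theta^[i] (global variable indices, ascending) and an output
# vector k of length 2^{N^[i]}: k[m + 1] is the update outcome when exactly
# the inputs flagged by local bit mask m are ON.  Deterministic rules have
# k in {0,1}; probabilistic rules store the likelihood that the target turns
# ON given each input pattern.

#' Construct a Boolean network from rule components
#'
#' Most users will call [parse_network()] or [generate_random_network()]
#' instead; this is the low-level constructor.
#'
#' @param variables character vector of unique variable names (fixed global
#'   order; indices are 1-based positions in this vector).
#' @param rules list, one element per variable, each a list with fields
#'   \code{inputs} (integer indices into \code{variables}, ascending) and
#'   \code{k} (numeric of length \code{2^length(inputs)}, indexed by local
#'   input bit mask, entries in \[0,1\]).
#' @param kind \code{"deterministic"} or \code{"probabilistic"}.
#' @param rates optional per-variable rates in \[0,1\] used by
#'   continuous-time simulation (see [close_system()]).
#' @return an object of class \code{boolean_network}.
#' @export
boolean_network <- function(variables, rules, kind = "deterministic",
                            rates = NULL) {
  variables <- as.character(variables)
  n <- length(variables)
  if (n < 1L) stop("a network needs at least one variable", call. = FALSE)
  if (n > .BOOLPOP_MAX_VARS) {
    stop("networks are limited to ", .BOOLPOP_MAX_VARS,
         " variables (subset masks are stored in doubles)", call. = FALSE)
  }
  if (anyDuplicated(variables)) {
    stop("duplicate variable names: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(rules) != n) stop("need exactly one rule per variable", call. = FALSE)
  kind <- match.arg(kind, c("deterministic", "probabilistic"))
  for (i in seq_len(n)) {
    r <- rules[[i]]
    r$inputs <- as.integer(r$inputs)
    if (length(r$inputs) && (is.unsorted(r$inputs, strictly = TRUE) ||
                             any(r$inputs < 1L) || any(r$inputs > n))) {
      stop("rule for '", variables[i],
           "': inputs must be strictly increasing indices of declared variables",
           call. = FALSE)
    }
    if (length(r$k) != 2^length(r$inputs)) {
      stop("rule for '", variables[i], "': k must have length 2^n_inputs",
           call. = FALSE)
    }
    if (any(r$k < 0 | r$k > 1)) {
      stop("rule for '", variables[i], "': k entries must lie in [0,1]",
           call. = FALSE)
    }
    if (kind == "deterministic" && !all(r$k %in% c(0, 1))) {
      stop("rule for '", variables[i],
           "': deterministic networks need 0/1 outputs", call. = FALSE)
    }
    r$k <- as.numeric(r$k)
    rules[[i]] <- r[c("inputs", "k")]
  }
  if (!is.null(rates)) {
    stopifnot(length(rates) == n, all(rates >= 0), all(rates <= 1))
    rates <- as.numeric(rates)
  }
  structure(list(variables = variables, rules = rules, kind = kind,
                 rates = rates),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network (", x$kind, "): ", length(x$variables),
      " variables\n", sep = "")
  for (i in seq_along(x$variables)) {
    r <- x$rules[[i]]
    cat("  ", x$variables[i], " <- f(",
        paste(x$variables[r$inputs], collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

n_variables <- function(net) length(net$variables)

.var_index <- function(net, var) {
  if (is.character(var)) {
    ix <- match(var, net$variables)
    if (anyNA(ix)) {
      stop("unknown variable(s): ", paste(var[is.na(ix)], collapse = ", "),
           call. = FALSE)
    }
    ix
  } else {
    ix <- as.integer(var)
    stopifnot(all(ix >= 1L), all(ix <= n_variables(net)))
    ix
  }
}

#' Truth table of one variable's update rule
#'
#' Returns the output vector \eqn{k^{[i]}} indexed by the input patterns of
#' variable \code{var}, in canonical subset order (by cardinality, then
#' lexicographic on the sorted inputs), with pattern labels as names.  For
#' the 3-node example network, variable B with inputs (A, C) yields
#' \code{c("0" = 0, A = 0, C = 0, A.C = 1)}.
#'
#' @param net a [boolean_network()].
#' @param var variable name or index.
#' @return named numeric vector of length \code{2^N_inputs}.
#' @export
truth_table <- function(net, var) {
  i <- .var_index(net, var)
  stopifnot(length(i) == 1L)
  r <- net$rules[[i]]
  n <- length(r$inputs)
  canon <- enumerate_subsets(n)
  k <- r$k[canon + 1]
  names(k) <- subset_label(canon, net$variables[r$inputs])
  k
}

# output of rule i under a full 0/1 network state (vectorised over rows of
# a state matrix); returns the k entry (probability or 0/1) per row
.rule_outputs <- function(net, states) {
  states <- matrix(states, ncol = n_variables(net))
  out <- matrix(0, nrow(states), n_variables(net))
  for (i in seq_len(n_variables(net))) {
    r <- net$rules[[i]]
    if (length(r$inputs) == 0L) {
      out[, i] <- r$k
    } else {
      m <- as.vector(states[, r$inputs, drop = FALSE] %*%
                       2^(seq_along(r$inputs) - 1L))
      out[, i] <- r$k[m + 1]
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Parsing and serialization (BoolNet-style "targets, factors" dialect).

.tokenize_expression <- function(expr_text, line_no) {
  txt <- gsub("\\bAND\\b", "&", expr_text, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
  ok <- gsub("[A-Za-z_][A-Za-z0-9_.]*|[()!&|[:space:]]|\\b[01]\\b", "", txt)
  if (nzchar(ok)) {
    stop("line ", line_no, ": unsupported token(s) '", ok, "' in rule '",
         expr_text, "'", call. = FALSE)
  }
  txt
}

.eval_expression_table <- function(parsed, vars_used, line_no) {
  n <- length(vars_used)
  if (n > 20L) {
    stop("line ", line_no, ": rule has ", n,
         " inputs; the per-rule cap is 20", call. = FALSE)
  }
  k <- numeric(2^n)
  env <- new.env(parent = baseenv())
  for (m in 0:(2^n - 1)) {
    bits <- (m %/% 2^(seq_len(n) - 1L)) %% 2 == 1
    for (j in seq_len(n)) assign(vars_used[j], bits[j], envir = env)
    val <- eval(parsed, env)
    k[m + 1] <- as.numeric(isTRUE(as.logical(val)) || identical(val, 1))
  }
  k
}

#' Parse a Boolean network from rules text
#'
#' Reads the BoolNet-style plain-text dialect: an optional
#' \code{targets, factors} header, then one rule per line,
#' \code{target, expression}, with operators \code{!}/\code{NOT},
#' \code{&}/\code{AND}, \code{|}/\code{OR}, parentheses and the constants
#' \code{0} and \code{1}.  Comment lines start with \code{#}.  An extension
#' line of the form
#' \preformatted{table: target, input1 input2 ..., k1 k2 ...}
#' declares an explicit output vector (needed for probabilistic rules), with
#' the k values listed in the canonical pattern order (cardinality, then
#' lexicographic) over the inputs as listed.
#'
#' A variable's input set is exactly the set of variables appearing in its
#' expression.  Referencing an undeclared variable, or declaring a target
#' twice, is an error.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param file alternatively, path to a rules file.
#' @return a [boolean_network()].
#' @export
#' @examples
#' net <- parse_network(c("A, !B", "B, A & C", "C, A | B"))
#' truth_table(net, "C")
parse_network <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  raw <- data.frame(no = seq_along(lines), txt = trimws(lines),
                    stringsAsFactors = FALSE)
  raw <- raw[nzchar(raw$txt) & !startsWith(raw$txt, "#"), , drop = FALSE]
  is_header <- tolower(gsub("[[:space:]]", "", raw$txt)) == "targets,factors"
  raw <- raw[!is_header, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no rules found", call. = FALSE)

  targets <- character(0)
  entries <- list()
  for (r in seq_len(nrow(raw))) {
    line <- raw$txt[r]
    no <- raw$no[r]
    if (startsWith(line, "table:")) {
      body <- sub("^table:", "", line)
      parts <- strsplit(body, ",", fixed = TRUE)[[1]]
      if (length(parts) != 3L) {
        stop("line ", no, ": table rule needs 'table: target, inputs, k'",
             call. = FALSE)
      }
      tgt <- trimws(parts[1])
      ins <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
      ins <- ins[nzchar(ins)]
      k <- as.numeric(strsplit(trimws(parts[3]), "[[:space:]]+")[[1]])
      if (anyNA(k) || length(k) != 2^length(ins)) {
        stop("line ", no, ": table rule needs 2^n_inputs numeric k values",
             call. = FALSE)
      }
      entries[[length(entries) + 1L]] <-
        list(target = tgt, form = "table", inputs = ins, k = k, no = no)
    } else {
      comma <- regexpr(",", line, fixed = TRUE)
      if (comma < 0) {
        stop("line ", no, ": expected 'target, expression'", call. = FALSE)
      }
      tgt <- trimws(substr(line, 1L, comma - 1L))
      rhs <- trimws(substr(line, comma + 1L, nchar(line)))
      entries[[length(entries) + 1L]] <-
        list(target = tgt, form = "expr", rhs = rhs, no = no)
    }
    if (tgt %in% targets) {
      stop("line ", no, ": duplicate rule for target '", tgt, "'",
           call. = FALSE)
    }
    targets <- c(targets, tgt)
  }

  rules <- vector("list", length(targets))
  kind <- "deterministic"
  for (e in entries) {
    i <- match(e$target, targets)
    if (e$form == "table") {
      ix <- match(e$inputs, targets)
      if (anyNA(ix)) {
        stop("line ", e$no, ": undeclared input variable(s): ",
             paste(e$inputs[is.na(ix)], collapse = ", "), call. = FALSE)
      }
      o <- order(ix)
      ix_sorted <- ix[o]
      # reorder k: from canonical order over given inputs to local-mask order
      # over sorted inputs
      n <- length(ix)
      canon_given <- enumerate_subsets(n)  # masks in the *given* input order
      k_local <- numeric(2^n)
      for (p in seq_along(canon_given)) {
        mg <- canon_given[p]
        pos_given <- mask_indices(mg, n)
        m_sorted <- mask_from_indices(match(ix[pos_given], ix_sorted))
        k_local[m_sorted + 1] <- e$k[p]
      }
      if (!all(k_local %in% c(0, 1))) kind <- "probabilistic"
      rules[[i]] <- list(inputs = ix_sorted, k = k_local)
    } else {
      txt <- .tokenize_expression(e$rhs, e$no)
      parsed <- tryCatch(parse(text = txt)[[1]],
                         error = function(err) {
                           stop("line ", e$no, ": cannot parse rule: ",
                                conditionMessage(err), call. = FALSE)
                         })
      used <- all.vars(parsed)
      ix <- match(used, targets)
      if (anyNA(ix)) {
        stop("line ", e$no, ": undeclared variable(s): ",
             paste(used[is.na(ix)], collapse = ", "), call. = FALSE)
      }
      o <- order(ix)
      vars_sorted <- used[o]
      k <- .eval_expression_table(parsed, vars_sorted, e$no)
      rules[[i]] <- list(inputs = ix[o], k = k)
    }
  }
  boolean_network(targets, rules, kind = kind)
}

#' Serialize a Boolean network to rules text
#'
#' \code{format = "table"} writes every rule as an explicit \code{table:}
#' line (lossless: reparsing returns an identical network).
#' \code{format = "expr"} writes deterministic rules as sum-of-products
#' logic expressions; rules whose output is constant are written as the
#' constant, which drops their (irrelevant) input list.  Probabilistic
#' rules are always written as \code{table:} lines.
#'
#' @param net a [boolean_network()].
#' @param format \code{"expr"} or \code{"table"}.
#' @param file optional path to write to.
#' @return character vector of lines, invisibly when \code{file} is given.
#' @export
serialize_network <- function(net, format = c("expr", "table"), file = NULL) {
  format <- match.arg(format)
  out <- "targets, factors"
  for (i in seq_along(net$variables)) {
    r <- net$rules[[i]]
    det <- all(r$k %in% c(0, 1))
    if (format == "table" || !det) {
      k_canon <- r$k[enumerate_subsets(length(r$inputs)) + 1]
      out <- c(out, paste0("table: ", net$variables[i], ", ",
                           paste(net$variables[r$inputs], collapse = " "),
                           ", ", paste(vapply(k_canon, function(v) {
                             if (v %% 1 == 0) format(v) else sprintf("%.17g", v)
                           }, character(1)), collapse = " ")))
    } else {
      out <- c(out, paste0(net$variables[i], ", ",
                           .rule_to_expression(net, i)))
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.rule_to_expression <- function(net, i) {
  r <- net$rules[[i]]
  n <- length(r$inputs)
  if (all(r$k == 0)) return("0")
  if (all(r$k == 1)) return("1")
  terms <- character(0)
  for (m in which(r$k == 1) - 1L) {
    bits <- (m %/% 2^(seq_len(n) - 1L)) %% 2 == 1
    lits <- ifelse(bits, net$variables[r$inputs],
                   paste0("!", net$variables[r$inputs]))
    terms <- c(terms, paste0("(", paste(lits, collapse = " & "), ")"))
  }
  paste(terms, collapse = " | ")
}

# ---------------------------------------------------------------------------
# Model augmentation.

#' Add wild-type knockout variables to a network
#'
#' For each listed gene A, appends a constant self-copying variable
#' \code{A.WT} and replaces A's rule g_A by \code{g_A & A.WT}.  Setting
#' \code{A.WT = 0} in an initial state then encodes a permanent
#' loss-of-function of A, so mixtures over wild-type states simulate
#' genetically heterogeneous populations.
#'
#' @param net a [boolean_network()].
#' @param genes variable names or indices to augment (no duplicates);
#'   defaults to all variables.
#' @return an augmented [boolean_network()] with \code{length(genes)} extra
#'   variables.
#' @export
augment_wildtype <- function(net, genes = net$variables) {
  if (length(genes) == 0L) return(net)
  ix <- .var_index(net, genes)
  if (anyDuplicated(ix)) {
    stop("gene(s) listed twice: ",
         paste(unique(net$variables[ix[duplicated(ix)]]), collapse = ", "),
         call. = FALSE)
  }
  n <- n_variables(net)
  wt_names <- paste0(net$variables[ix], ".WT")
  if (any(wt_names %in% net$variables)) {
    stop("wild-type name collision: ",
         paste(intersect(wt_names, net$variables), collapse = ", "),
         call. = FALSE)
  }
  variables <- c(net$variables, wt_names)
  rules <- net$rules
  for (g in seq_along(ix)) {
    i <- ix[g]
    wt_index <- n + g
    r <- rules[[i]]
    # wt gets the highest index, hence the top local bit: the first half of
    # the new k (WT off) is all zeros, the second half is the old k
    rules[[i]] <- list(inputs = c(r$inputs, wt_index),
                       k = c(numeric(length(r$k)), r$k))
    rules[[wt_index]] <- list(inputs = wt_index, k = c(0, 1))
  }
  boolean_network(variables, rules, kind = net$kind, rates = net$rates)
}

#' Wild-type pairing of an augmented network
#'
#' @param net an augmented network.
#' @return integer vector over variables: the index of each gene's
#'   \code{.WT} partner, or NA for variables without one (including the WT
#'   variables themselves).
#' @keywords internal
wildtype_partner <- function(net) {
  match(paste0(net$variables, ".WT"), net$variables)
}

#' Augment a deterministic network with per-variable update rates
#'
#' Produces the probabilistic network in which variable i keeps its current
#' state with probability 1 - r_i and applies its logic rule with
#' probability r_i, i.e. the single-variable update becomes
#' f'_i = (1 - r_i) x_i + r_i f_i.  r_i = 1 reproduces the deterministic
#' update; r_i = 0 freezes the variable.
#'
#' @param net a deterministic [boolean_network()].
#' @param rates numeric vector of per-variable rates in \[0,1\] (recycled
#'   if length 1).
#' @return a probabilistic [boolean_network()].
#' @export
attach_rates <- function(net, rates) {
  if (net$kind != "deterministic") {
    stop("attach_rates() expects a deterministic network", call. = FALSE)
  }
  n <- n_variables(net)
  rates <- rep_len(as.numeric(rates), n)
  if (any(rates < 0 | rates > 1) || anyNA(rates)) {
    stop("rates must lie in [0,1]", call. = FALSE)
  }
  rules <- vector("list", n)
  for (i in seq_len(n)) {
    r <- net$rules[[i]]
    inputs_new <- sort(unique(c(r$inputs, i)))
    nn <- length(inputs_new)
    pos_old <- match(r$inputs, inputs_new)
    pos_self <- match(i, inputs_new)
    m <- 0:(2^nn - 1)
    bits <- vapply(seq_len(nn), function(j) (m %/% 2^(j - 1)) %% 2,
                   numeric(2^nn))
    bits <- matrix(bits, ncol = nn)
    old_mask <- if (length(pos_old)) {
      as.vector(bits[, pos_old, drop = FALSE] %*% 2^(seq_along(pos_old) - 1L))
    } else {
      rep(0, 2^nn)
    }
    k_new <- (1 - rates[i]) * bits[, pos_self] + rates[i] * r$k[old_mask + 1]
    rules[[i]] <- list(inputs = inputs_new, k = k_new)
  }
  boolean_network(net$variables, rules, kind = "probabilistic", rates = rates)
}

#' Read a per-variable rate vector from a two-column TSV
#'
#' @param file path to a TSV with columns \code{variable} and \code{rate}.
#' @param net network whose variable order the rates are matched against.
#' @return numeric vector of rates aligned to \code{net$variables};
#'   variables absent from the file default to 1.
#' @export
read_rates <- function(file, net) {
  tab <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("variable", "rate") %in% names(tab))) {
    stop("rate file needs columns 'variable' and 'rate'", call. = FALSE)
  }
  ix <- .var_index(net, tab$variable)
  r <- rep(1, n_variables(net))
  r[ix] <- as.numeric(tab$rate)
  if (any(r < 0 | r > 1) || anyNA(r)) stop("rates must lie in [0,1]", call. = FALSE)
  r
}

# ---------------------------------------------------------------------------
# Random test networks.

#' Generate a random Boolean network
#'
#' Each variable draws its in-degree uniformly from \code{in_degree}, picks
#' that many distinct input variables uniformly, and fills its truth table
#' with independent fair coin flips.  With the defaults (10 variables,
#' in-degree 1-4) the expected edge count is 25.
#'
#' @param n_vars number of variables.
#' @param in_degree length-2 integer range (inclusive) for per-variable
#'   in-degree.
#' @param seed optional integer seed; the generator is fully reproducible
#'   from it and restores the caller's RNG state on exit.
#' @param allow_self_inputs may a variable take input from itself?
#' @param force_nondegenerate if TRUE, truth tables are redrawn until they
#'   depend on every listed input.
#' @return a deterministic [boolean_network()]; the generator settings are
#'   recorded in \code{attr(net, "provenance")}.
#' @export
generate_random_network <- function(n_vars = 10L, in_degree = c(1L, 4L),
                                    seed = NULL, allow_self_inputs = TRUE,
                                    force_nondegenerate = FALSE) {
  stopifnot(n_vars >= 1L, length(in_degree) %in% c(1L, 2L))
  in_degree <- as.integer(range(in_degree))
  if (in_degree[1] < 1L || in_degree[2] > n_vars) {
    stop("in-degree range must lie within [1, n_vars]", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  variables <- if (n_vars <= 26L) {
    LETTERS[seq_len(n_vars)]
  } else {
    sprintf("v%02d", seq_len(n_vars))
  }
  rules <- vector("list", n_vars)
  for (i in seq_len(n_vars)) {
    pool <- if (allow_self_inputs) seq_len(n_vars) else setdiff(seq_len(n_vars), i)
    deg <- if (in_degree[1] == in_degree[2]) {
      in_degree[1]
    } else {
      sample(seq(in_degree[1], in_degree[2]), 1L)
    }
    deg <- min(deg, length(pool))
    inputs <- sort(sample(pool, deg))
    repeat {
      k <- sample(c(0, 1), 2^deg, replace = TRUE)
      if (!force_nondegenerate || .depends_on_all(k, deg)) break
    }
    rules[[i]] <- list(inputs = inputs, k = k)
  }
  net <- boolean_network(variables, rules, kind = "deterministic")
  attr(net, "provenance") <- list(generator = "generate_random_network",
                                  n_vars = n_vars, in_degree = in_degree,
                                  seed = seed,
                                  allow_self_inputs = allow_self_inputs,
                                  force_nondegenerate = force_nondegenerate)
  net
}

.depends_on_all <- function(k, n) {
  if (n == 0L) return(TRUE)
  m <- 0:(2^n - 1)
  for (j in seq_len(n) - 1L) {
    hi <- bitwAnd(m, bitwShiftL(1L, j)) != 0L
    if (all(k[hi] == k[!hi])) return(FALSE)
  }
  TRUE
}
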