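#' Minimal SMILES context-free grammar
#'
#' A small production-rule grammar over SMILES tokens (atoms, bonds, ring
#' bond digits, branches), in the grammar-VAE style: a molecule is parsed to
#' its leftmost-derivation production sequence, and that rule sequence is
#' what gets one-hot encoded. The grammar is deliberately minimal - it
#' covers organic-subset atoms, double/triple bonds, ring closures and
#' nested branches, which is everything the built-in fragment vocabulary of
#' [generate_library()] can emit.
#'
#' Nonterminals: `S` (chain), `U` (chain unit), `E` (bond edge), `A` (atom),
#' `F` (suffix list), `G` (single suffix: ring digit or branch), `R` (ring
#' digit). Rules are ordered and indexed deterministically; the padding rule
#' is always last (`vocabulary_size = n_rules + 1`).
#'
#' @param max_sequence_length maximum rule-sequence length an encoding may
#'   occupy (rows of the one-hot matrix), default 96.
#' @return object of class `smiles_grammar`.
#' @export
smiles_grammar <- function(max_sequence_length = 96L) {
  max_sequence_length <- check_scalar_count(max_sequence_length, "max_sequence_length")
  atoms <- c("C", "c", "N", "n", "O", "o", "P", "S", "s", "F", "Cl", "Br", "I")
  # nonterminal symbols are bracketed so they can never collide with the
  # atom tokens S (sulfur) and F (fluorine)
  rules <- c(
    list(
      list(lhs = "<S>", rhs = c("<U>", "<S>")),
      list(lhs = "<S>", rhs = "<U>"),
      list(lhs = "<U>", rhs = c("<A>", "<F>")),
      list(lhs = "<U>", rhs = "<A>"),
      list(lhs = "<U>", rhs = c("<E>", "<A>", "<F>")),
      list(lhs = "<U>", rhs = c("<E>", "<A>")),
      list(lhs = "<E>", rhs = "="),
      list(lhs = "<E>", rhs = "#")
    ),
    lapply(atoms, function(a) list(lhs = "<A>", rhs = a)),
    list(
      list(lhs = "<F>", rhs = c("<G>", "<F>")),
      list(lhs = "<F>", rhs = "<G>"),
      list(lhs = "<G>", rhs = "<R>"),
      list(lhs = "<G>", rhs = c("(", "<S>", ")"))
    ),
    lapply(as.character(1:9), function(d) list(lhs = "<R>", rhs = d))
  )
  structure(list(
    production_rules = rules,
    n_rules = length(rules),
    vocabulary_size = length(rules) + 1L,   # + padding rule
    padding_index = length(rules) + 1L,
    nonterminals = c("<S>", "<U>", "<E>", "<A>", "<F>", "<G>", "<R>"),
    atom_tokens = atoms,
    max_sequence_length = max_sequence_length
  ), class = "smiles_grammar")
}

#' @export
print.smiles_grammar <- function(x, ...) {
  cat(sprintf("<smiles_grammar> %d production rules + padding (vocabulary %d), max length %d\n",
              x$n_rules, x$vocabulary_size, x$max_sequence_length))
  invisible(x)
}

# greedy tokenizer; two-character atoms first
tokenize_smiles <- function(smiles) {
  singles <- c("C", "c", "N", "n", "O", "o", "P", "S", "s", "F", "I",
               "=", "#", "(", ")", as.character(1:9))
  tokens <- character(0)
  i <- 1L
  nchars <- nchar(smiles)
  while (i <= nchars) {
    two <- substr(smiles, i, i + 1L)
    one <- substr(smiles, i, i)
    if (two %in% c("Cl", "Br")) {
      tokens <- c(tokens, two); i <- i + 2L
    } else if (one %in% singles) {
      tokens <- c(tokens, one); i <- i + 1L
    } else {
      stop(sprintf("SMILES parse error: unsupported character '%s' at position %d", one, i),
           call. = FALSE)
    }
  }
  tokens
}

#' Parse a SMILES string to its production-rule sequence
#'
#' Tokenizes and parses `smiles` under `grammar`, returning the
#' leftmost-derivation rule-index sequence (preorder over the derivation
#' tree). Replaying the sequence with [sequence_to_smiles()] regenerates the
#' input string exactly. Syntax errors (unsupported characters, dangling
#' bonds, unbalanced parentheses, unclosed ring bonds) raise a parse error
#' with the offending token position; sequences longer than
#' `grammar$max_sequence_length` raise a length error.
#'
#' @param smiles a SMILES string.
#' @param grammar a [smiles_grammar()].
#' @return integer vector of rule indices.
#' @export
parse_to_rule_sequence <- function(smiles, grammar = smiles_grammar()) {
  tokens <- tokenize_smiles(smiles)
  if (length(tokens) == 0L) {
    stop("SMILES parse error: empty string", call. = FALSE)
  }
  check_ring_closures(tokens)
  atoms <- grammar$atom_tokens
  digits <- as.character(1:9)
  rule_for <- function(lhs, rhs1) {
    for (k in seq_len(grammar$n_rules)) {
      r <- grammar$production_rules[[k]]
      if (r$lhs == lhs && r$rhs[1L] == rhs1 && length(r$rhs) == 1L) return(k)
    }
    stop(sprintf("SMILES parse error: no %s rule for token '%s'", lhs, rhs1), call. = FALSE)
  }
  rule_idx <- function(lhs, rhs) {
    for (k in seq_len(grammar$n_rules)) {
      r <- grammar$production_rules[[k]]
      if (r$lhs == lhs && identical(r$rhs, rhs)) return(k)
    }
    stop("internal grammar error", call. = FALSE)
  }
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  consume <- function(expected = NULL) {
    if (pos > length(tokens)) {
      stop("SMILES parse error: unexpected end of input", call. = FALSE)
    }
    tok <- tokens[pos]
    if (!is.null(expected) && tok != expected) {
      stop(sprintf("SMILES parse error: expected '%s' at token %d, got '%s'",
                   expected, pos, tok), call. = FALSE)
    }
    pos <<- pos + 1L
    tok
  }
  starts_unit <- function(tok) !is.na(tok) && (tok %in% atoms || tok %in% c("=", "#"))
  starts_suffix <- function(tok) !is.na(tok) && (tok %in% digits || tok == "(")

  parse_A <- function() {
    tok <- peek()
    if (is.na(tok) || !(tok %in% atoms)) {
      stop(sprintf("SMILES parse error: expected atom at token %d, got '%s'",
                   pos, if (is.na(tok)) "<end>" else tok), call. = FALSE)
    }
    consume()
    list(rule = rule_for("<A>", tok), children = list())
  }
  parse_E <- function() {
    tok <- consume()
    list(rule = rule_for("<E>", tok), children = list())
  }
  parse_R <- function() {
    tok <- peek()
    if (is.na(tok) || !(tok %in% digits)) {
      stop(sprintf("SMILES parse error: expected ring digit at token %d", pos), call. = FALSE)
    }
    consume()
    list(rule = rule_for("<R>", tok), children = list())
  }
  parse_G <- function() {
    tok <- peek()
    if (!is.na(tok) && tok == "(") {
      consume("(")
      s <- parse_S()
      consume(")")
      list(rule = rule_idx("<G>", c("(", "<S>", ")")), children = list(s))
    } else {
      list(rule = rule_idx("<G>", "<R>"), children = list(parse_R()))
    }
  }
  parse_F <- function() {
    g <- parse_G()
    if (starts_suffix(peek())) {
      list(rule = rule_idx("<F>", c("<G>", "<F>")), children = list(g, parse_F()))
    } else {
      list(rule = rule_idx("<F>", "<G>"), children = list(g))
    }
  }
  parse_U <- function() {
    tok <- peek()
    if (!is.na(tok) && tok %in% c("=", "#")) {
      e <- parse_E()
      a <- parse_A()
      if (starts_suffix(peek())) {
        list(rule = rule_idx("<U>", c("<E>", "<A>", "<F>")), children = list(e, a, parse_F()))
      } else {
        list(rule = rule_idx("<U>", c("<E>", "<A>")), children = list(e, a))
      }
    } else {
      a <- parse_A()
      if (starts_suffix(peek())) {
        list(rule = rule_idx("<U>", c("<A>", "<F>")), children = list(a, parse_F()))
      } else {
        list(rule = rule_idx("<U>", "<A>"), children = list(a))
      }
    }
  }
  parse_S <- function() {
    u <- parse_U()
    if (starts_unit(peek())) {
      list(rule = rule_idx("<S>", c("<U>", "<S>")), children = list(u, parse_S()))
    } else {
      list(rule = rule_idx("<S>", "<U>"), children = list(u))
    }
  }

  tree <- parse_S()
  if (pos <= length(tokens)) {
    stop(sprintf("SMILES parse error: unexpected token '%s' at token %d",
                 tokens[pos], pos), call. = FALSE)
  }
  seq <- flatten_preorder(tree)
  if (length(seq) > grammar$max_sequence_length) {
    stop(sprintf("SMILES length error: rule sequence length %d exceeds max_sequence_length %d",
                 length(seq), grammar$max_sequence_length), call. = FALSE)
  }
  seq
}

check_ring_closures <- function(tokens) {
  digits <- as.character(1:9)
  open <- stats::setNames(rep(FALSE, 9L), digits)
  opened_at <- stats::setNames(rep(NA_integer_, 9L), digits)
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% digits) {
      if (open[[tok]]) {
        open[[tok]] <- FALSE
      } else {
        open[[tok]] <- TRUE
        opened_at[[tok]] <- i
      }
    }
  }
  if (any(open)) {
    d <- names(which(open))[1L]
    stop(sprintf("SMILES parse error: unclosed ring bond '%s' opened at token %d",
                 d, opened_at[[d]]), call. = FALSE)
  }
  invisible(TRUE)
}

flatten_preorder <- function(node) {
  c(node$rule, unlist(lapply(node$children, flatten_preorder), use.names = FALSE))
}

#' Replay a rule sequence back to a SMILES string
#'
#' Expands the leftmost nonterminal with each successive rule of the
#' sequence; the terminal yield is the reconstructed SMILES. Inverse of
#' [parse_to_rule_sequence()].
#'
#' @param sequence integer rule-index sequence.
#' @param grammar a [smiles_grammar()].
#' @return a SMILES string.
#' @export
sequence_to_smiles <- function(sequence, grammar = smiles_grammar()) {
  nts <- grammar$nonterminals
  stack <- list("<S>")  # top = end of list
  out <- character(0)
  for (ri in sequence) {
    if (ri == grammar$padding_index) break
    if (ri < 1L || ri > grammar$n_rules) {
      stop(sprintf("replay error: rule index %d out of range", ri), call. = FALSE)
    }
    # shift leading terminals to the output
    while (length(stack) > 0L && !(stack[[length(stack)]] %in% nts)) {
      out <- c(out, stack[[length(stack)]])
      stack[[length(stack)]] <- NULL
    }
    if (length(stack) == 0L) {
      stop("replay error: rule supplied but no nonterminal left to expand", call. = FALSE)
    }
    rule <- grammar$production_rules[[ri]]
    top <- stack[[length(stack)]]
    if (top != rule$lhs) {
      stop(sprintf("replay error: rule %d expands '%s' but leftmost nonterminal is '%s'",
                   ri, rule$lhs, top), call. = FALSE)
    }
    stack[[length(stack)]] <- NULL
    for (sym in rev(rule$rhs)) stack[[length(stack) + 1L]] <- sym
  }
  while (length(stack) > 0L) {
    sym <- stack[[length(stack)]]
    if (sym %in% nts) {
      stop("replay error: rule sequence ended with unexpanded nonterminals", call. = FALSE)
    }
    out <- c(out, sym)
    stack[[length(stack)]] <- NULL
  }
  paste(out, collapse = "")
}

#' One-hot encode a rule sequence
#'
#' Row `r` of the result is the one-hot vector of `sequence[r]`; rows past
#' the sequence length carry the padding rule. Every row sums to exactly 1.
#' `decode_one_hot()` inverts the encoding.
#'
#' @param sequence integer rule-index sequence.
#' @param grammar a [smiles_grammar()].
#' @return `max_sequence_length x vocabulary_size` binary matrix.
#' @export
one_hot <- function(sequence, grammar = smiles_grammar()) {
  L <- grammar$max_sequence_length
  V <- grammar$vocabulary_size
  if (length(sequence) > L) {
    stop(sprintf("encoding length error: sequence length %d exceeds max_sequence_length %d",
                 length(sequence), L), call. = FALSE)
  }
  if (length(sequence) > 0L && (any(sequence < 1L) || any(sequence > V))) {
    stop("encoding error: rule index out of range", call. = FALSE)
  }
  m <- matrix(0L, nrow = L, ncol = V)
  idx <- c(sequence, rep(grammar$padding_index, L - length(sequence)))
  m[cbind(seq_len(L), idx)] <- 1L
  m
}

#' @rdname one_hot
#' @param encoding a one-hot matrix produced by [one_hot()].
#' @export
decode_one_hot <- function(encoding, grammar = smiles_grammar()) {
  if (!all(rowSums(encoding) == 1L)) {
    stop("decode error: every one-hot row must sum to 1", call. = FALSE)
  }
  idx <- max.col(encoding, ties.method = "first")
  pad <- which(idx == grammar$padding_index)
  if (length(pad) > 0L) idx <- idx[seq_len(pad[1L] - 1L)]
  as.integer(idx)
}

#' One-hot encode a set of SMILES into a flattened matrix
#'
#' Convenience path used by the VAE: parse each SMILES, one-hot encode, and
#' flatten (column-major) into one row of an `n x (L*V)` numeric matrix.
#'
#' @param smiles character vector of SMILES strings.
#' @param grammar a [smiles_grammar()].
#' @return numeric matrix, rownames from `names(smiles)` if present.
#' @export
one_hot_matrix <- function(smiles, grammar = smiles_grammar()) {
  rows <- vapply(smiles, function(s) {
    as.numeric(one_hot(parse_to_rule_sequence(s, grammar), grammar))
  }, numeric(grammar$max_sequence_length * grammar$vocabulary_size))
  m <- t(rows)
  rownames(m) <- names(smiles)
  m
}
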