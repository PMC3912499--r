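// Core of the grammatical-evolution search: genotype->phenotype mapping,
// compilation of derived expressions to a stack program, vectorised
// evaluation with balanced-accuracy fitness, and the per-deme generation
// loop. Kept in C++ because the search evaluates millions of candidate
// networks per run.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cstdlib>
#include <cmath>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// Small deterministic PCG32 generator so every deme owns an independent
// stream (seed-stable results regardless of execution order/parallelism).
struct Pcg32 {
  uint64_t state, inc;
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Pcg32(uint64_t seed) {
    uint64_t s = seed;
    state = splitmix64(s);
    inc = splitmix64(s) | 1ULL;
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform double in [0,1): 32 bits
  double runif01() { return next() * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(next() % (uint32_t)n); }
};

// ------------------------------------------------------------- grammar ----
struct GrammarEnc {
  // rules[j] = alternatives; each alternative a vector of symbols:
  // positive k = terminal id (1-based), negative j = non-terminal (1-based)
  std::vector<std::vector<std::vector<int> > > rules;
  int start;            // 1-based non-terminal index
  int var_terminal;     // terminal id of %var%, 0 if absent
  int n_variables;
  // terminal semantics for the expression language
  std::vector<int> opcode;      // 1=PADD 2=PSUB 3=PMULT 4=PDIV, 0 otherwise
  std::vector<int> punct;       // 1:'(' 2:')' 3:',' 4:'*', 0 otherwise
  std::vector<char> numchar;    // single numeric char ('0'-'9','.','-'), else 0
};

static GrammarEnc build_enc(const List &enc) {
  GrammarEnc g;
  List rules = enc["rules"];
  for (int i = 0; i < rules.size(); ++i) {
    List alts = rules[i];
    std::vector<std::vector<int> > av;
    for (int a = 0; a < alts.size(); ++a) {
      IntegerVector sy = alts[a];
      av.push_back(std::vector<int>(sy.begin(), sy.end()));
    }
    g.rules.push_back(av);
  }
  g.start = as<int>(enc["start"]);
  g.var_terminal = as<int>(enc["var_terminal"]);
  g.n_variables = as<int>(enc["n_variables"]);
  CharacterVector terms = enc["terminals"];
  int nt = terms.size();
  g.opcode.assign(nt + 1, 0);
  g.punct.assign(nt + 1, 0);
  g.numchar.assign(nt + 1, 0);
  for (int t = 0; t < nt; ++t) {
    std::string s = as<std::string>(terms[t]);
    int id = t + 1;
    if (s == "PADD") g.opcode[id] = 1;
    else if (s == "PSUB") g.opcode[id] = 2;
    else if (s == "PMULT") g.opcode[id] = 3;
    else if (s == "PDIV") g.opcode[id] = 4;
    else if (s == "(") g.punct[id] = 1;
    else if (s == ")") g.punct[id] = 2;
    else if (s == ",") g.punct[id] = 3;
    else if (s == "*") g.punct[id] = 4;
    else if (s.size() == 1 &&
             (std::strchr("0123456789.-", s[0]) != NULL)) g.numchar[id] = s[0];
  }
  return g;
}

// ------------------------------------------------------------- mapping ----
// Leftmost derivation; tokens: terminal id (>0) or -(variable index 1..p).
// Returns true when mapping completed within the wrap budget.
static bool map_codons(const std::vector<int> &codons, const GrammarEnc &g,
                       int max_wraps, std::vector<int> &tokens,
                       int &codons_used, int &wraps_used) {
  tokens.clear();
  codons_used = 0;
  wraps_used = 0;
  const int len = (int)codons.size();
  int pos = 0;
  bool failed = false;
  // next codon with wrapping
  struct Reader {
    const std::vector<int> &c; int &pos, &wraps, &used;
    int len, max_wraps; bool &failed;
    int next() {
      if (pos >= len) {
        if (wraps >= max_wraps) { failed = true; return 0; }
        ++wraps; pos = 0;
      }
      ++used;
      return c[pos++];
    }
  } rd{codons, pos, wraps_used, codons_used, len, max_wraps, failed};

  std::vector<int> stack;
  stack.push_back(-g.start);
  long steps = 0;
  const long max_steps = 200000;
  while (!stack.empty()) {
    if (++steps > max_steps || (long)tokens.size() > 100000) return false;
    int sym = stack.back();
    stack.pop_back();
    if (sym < 0) {
      const std::vector<std::vector<int> > &alts = g.rules[-sym - 1];
      int n_alts = (int)alts.size();
      int choice = 0;
      if (n_alts > 1) {
        int c = rd.next();
        if (failed) return false;
        choice = c % n_alts;
      }
      const std::vector<int> &rhs = alts[choice];
      for (int i = (int)rhs.size() - 1; i >= 0; --i) stack.push_back(rhs[i]);
    } else {
      if (sym == g.var_terminal && g.var_terminal > 0) {
        int c1 = rd.next(); if (failed) return false;
        int c2 = rd.next(); if (failed) return false;
        int v = (c1 * 256 + c2) % g.n_variables;
        tokens.push_back(-(v + 1));
      } else {
        tokens.push_back(sym);
      }
    }
  }
  return true;
}

// ------------------------------------------------------------- compile ----
// Stack program over the canonical expression language
// OP(w*arg, w*arg[, w*arg]) with nested nodes.
enum { I_LOADVAR = 1, I_SCALE = 2, I_APPLY = 3 };
struct Instr { int op; int a; int b; double w; };

struct Compiler {
  const std::vector<int> &tok;
  const GrammarEnc &g;
  size_t pos;
  bool ok;
  int n_nodes;
  std::vector<Instr> prog;
  Compiler(const std::vector<int> &t, const GrammarEnc &gr)
    : tok(t), g(gr), pos(0), ok(true), n_nodes(0) {}
  int cur() const { return pos < tok.size() ? tok[pos] : 0; }
  bool is_punct(int p) const { int c = cur(); return c > 0 && g.punct[c] == p; }
  void node() {
    int c = cur();
    if (!(c > 0 && g.opcode[c] > 0)) { ok = false; return; }
    int op = g.opcode[c]; ++pos;
    if (!is_punct(1)) { ok = false; return; }
    ++pos;
    int arity = 0;
    while (ok) {
      winput();
      ++arity;
      if (is_punct(3)) { ++pos; continue; }
      break;
    }
    if (!ok) return;
    if (!is_punct(2) || arity < 1 || arity > 8) { ok = false; return; }
    ++pos;
    ++n_nodes;
    Instr in; in.op = I_APPLY; in.a = op; in.b = arity; in.w = 0.0;
    prog.push_back(in);
  }
  void winput() {
    char buf[64];
    int bl = 0;
    while (ok) {
      int c = cur();
      if (c > 0 && g.numchar[c] && bl < 60) { buf[bl++] = g.numchar[c]; ++pos; }
      else break;
    }
    if (bl == 0 || !is_punct(4)) { ok = false; return; }
    ++pos;
    buf[bl] = '\0';
    double w = std::strtod(buf, NULL);
    int c = cur();
    if (c < 0) {
      Instr in; in.op = I_LOADVAR; in.a = -c - 1; in.b = 0; in.w = 0.0;
      prog.push_back(in);
      ++pos;
    } else {
      node();
      if (!ok) return;
    }
    Instr sc; sc.op = I_SCALE; sc.a = 0; sc.b = 0; sc.w = w;
    prog.push_back(sc);
  }
  bool compile() {
    node();
    return ok && pos == tok.size();
  }
};

// ------------------------------------------------------------ evaluate ----
static const double PROTECT = 1.0;
static const double DIV_EPS = 1e-10;

static inline double guard(double x) { return R_finite(x) ? x : PROTECT; }
static inline double pdiv(double a, double b) {
  return (b >= DIV_EPS || b <= -DIV_EPS) ? a / b : PROTECT;
}

// Evaluate program over all samples; out must have length n.
static void eval_program(const std::vector<Instr> &prog,
                         const NumericMatrix &X,
                         std::vector<std::vector<double> > &stack,
                         std::vector<double> &out) {
  const int n = X.nrow();
  int sp = 0;
  for (size_t k = 0; k < prog.size(); ++k) {
    const Instr &in = prog[k];
    if (in.op == I_LOADVAR) {
      if ((int)stack.size() <= sp) stack.push_back(std::vector<double>(n));
      std::vector<double> &dst = stack[sp++];
      dst.resize(n);
      const double *col = &X(0, in.a);
      for (int i = 0; i < n; ++i) dst[i] = col[i];
    } else if (in.op == I_SCALE) {
      std::vector<double> &v = stack[sp - 1];
      const double w = in.w;
      for (int i = 0; i < n; ++i) v[i] = guard(v[i] * w);
    } else { // I_APPLY
      const int arity = in.b, op = in.a;
      std::vector<double> &dst = stack[sp - arity];
      for (int i = 0; i < n; ++i) {
        double acc = dst[i];
        if (op == 1) {        // PADD
          for (int a = 1; a < arity; ++a) acc += stack[sp - arity + a][i];
        } else if (op == 2) { // PSUB
          for (int a = 1; a < arity; ++a) acc -= stack[sp - arity + a][i];
        } else if (op == 3) { // PMULT
          for (int a = 1; a < arity; ++a) acc *= stack[sp - arity + a][i];
        } else {              // PDIV, protected left fold
          for (int a = 1; a < arity; ++a) acc = pdiv(acc, stack[sp - arity + a][i]);
        }
        dst[i] = guard(acc);
      }
      sp -= arity - 1;
    }
  }
  out.resize(n);
  for (int i = 0; i < n; ++i) out[i] = stack[0][i];
}

// Balanced accuracy of sign-threshold predictions (output >= 0 -> class 1).
static double fitness_ba(const std::vector<double> &out, const IntegerVector &y) {
  int tp = 0, fn = 0, tn = 0, fp = 0;
  const int n = y.size();
  for (int i = 0; i < n; ++i) {
    int pred = out[i] >= 0.0 ? 1 : 0;
    if (y[i] == 1) { if (pred == 1) ++tp; else ++fn; }
    else           { if (pred == 1) ++fp; else ++tn; }
  }
  if (tp + fn == 0 || tn + fp == 0) return 0.5;
  double sens = (double)tp / (tp + fn);
  double spec = (double)tn / (tn + fp);
  return 0.5 * (sens + spec);
}

// Map + compile + evaluate one genome; returns fitness (0 when invalid).
static double evaluate_genome(const std::vector<int> &codons, const GrammarEnc &g,
                              int max_wraps, const NumericMatrix &X,
                              const IntegerVector &y,
                              std::vector<std::vector<double> > &stack,
                              std::vector<double> &out,
                              std::vector<int> &tokens, int &n_nodes,
                              bool &valid) {
  int used, wraps;
  valid = false;
  n_nodes = 0;
  if (!map_codons(codons, g, max_wraps, tokens, used, wraps)) return 0.0;
  Compiler cc(tokens, g);
  if (!cc.compile()) return 0.0;
  valid = true;
  n_nodes = cc.n_nodes;
  eval_program(cc.prog, X, stack, out);
  return fitness_ba(out, y);
}

// Per-codon uniform mutation; geometric skips between mutated positions so
// the RNG cost scales with the number of mutations, not the genome length.
static void mutate_codons(std::vector<int> &g, double p, Pcg32 &rng) {
  if (p <= 0.0) return;
  const size_t n = g.size();
  if (p >= 1.0) {
    for (size_t k = 0; k < n; ++k) g[k] = rng.below(256);
    return;
  }
  const double denom = std::log(1.0 - p);
  double j = std::floor(std::log(1.0 - rng.runif01()) / denom);
  while (j < (double)n) {
    g[(size_t)j] = rng.below(256);
    j += 1.0 + std::floor(std::log(1.0 - rng.runif01()) / denom);
  }
}

// ---------------------------------------------------- random functional ----
// Depth-bounded random derivation growth emitting, in leftmost order, codons
// that reproduce the chosen derivation (so mapping the genome is guaranteed
// to succeed with zero wraps).
struct Grower {
  const GrammarEnc &g;
  Pcg32 &rng;
  std::vector<double> min_steps;  // per non-terminal; Inf-free by validation
  std::vector<int> out;
  Grower(const GrammarEnc &gr, Pcg32 &r) : g(gr), rng(r) {
    size_t nr = g.rules.size();
    min_steps.assign(nr, 1e9);
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t j = 0; j < nr; ++j) {
        double best = 1e9;
        for (size_t a = 0; a < g.rules[j].size(); ++a) {
          double worst = 0.0;
          for (size_t s = 0; s < g.rules[j][a].size(); ++s) {
            int sym = g.rules[j][a][s];
            if (sym < 0) worst = std::max(worst, min_steps[-sym - 1]);
          }
          best = std::min(best, 1.0 + worst);
        }
        if (best < min_steps[j]) { min_steps[j] = best; changed = true; }
      }
    }
  }
  void emit_alt(int alt, int n_alts) {
    int count = (255 - alt) / n_alts + 1;
    out.push_back(alt + n_alts * rng.below(count));
  }
  void emit_var() {
    int v = rng.below(g.n_variables);
    int count = (65535 - v) / g.n_variables + 1;
    int u = v + g.n_variables * rng.below(count);
    out.push_back(u / 256);
    out.push_back(u % 256);
  }
  void grow(int rule, int budget) {
    const std::vector<std::vector<int> > &alts = g.rules[rule];
    int n_alts = (int)alts.size();
    std::vector<int> feas;
    for (int a = 0; a < n_alts; ++a) {
      bool ok = true;
      for (size_t s = 0; s < alts[a].size() && ok; ++s) {
        int sym = alts[a][s];
        if (sym < 0 && min_steps[-sym - 1] > budget - 1) ok = false;
      }
      if (ok) feas.push_back(a);
    }
    if (feas.empty()) stop("depth budget cannot terminate grammar rule");
    int choice = feas[feas.size() == 1 ? 0 : rng.below((int)feas.size())];
    if (n_alts > 1) emit_alt(choice, n_alts);
    for (size_t s = 0; s < alts[choice].size(); ++s) {
      int sym = alts[choice][s];
      if (sym < 0) grow(-sym - 1, budget - 1);
      else if (sym == g.var_terminal && g.var_terminal > 0) emit_var();
    }
  }
};

// [[Rcpp::export]]
List cpp_random_genomes(List enc, int n, int max_depth, double seed) {
  GrammarEnc g = build_enc(enc);
  Pcg32 rng((uint64_t)seed);
  Grower gw(g, rng);
  List out(n);
  for (int i = 0; i < n; ++i) {
    gw.out.clear();
    gw.grow(g.start - 1, max_depth);
    out[i] = IntegerVector(gw.out.begin(), gw.out.end());
  }
  return out;
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
List cpp_map_genome(IntegerVector genome, List enc, int max_wraps) {
  GrammarEnc g = build_enc(enc);
  std::vector<int> codons(genome.begin(), genome.end());
  std::vector<int> tokens;
  int used = 0, wraps = 0;
  bool ok = map_codons(codons, g, max_wraps, tokens, used, wraps);
  return List::create(_["valid"] = ok,
                      _["tokens"] = IntegerVector(tokens.begin(), tokens.end()),
                      _["codons_used"] = used,
                      _["wraps_used"] = wraps);
}

// [[Rcpp::export]]
NumericVector cpp_evaluate_population(List genomes, NumericMatrix X,
                                      IntegerVector y, List enc, int max_wraps) {
  GrammarEnc g = build_enc(enc);
  int np = genomes.size();
  NumericVector fit(np);
  std::vector<std::vector<double> > stack;
  std::vector<double> out;
  std::vector<int> tokens;
  for (int i = 0; i < np; ++i) {
    IntegerVector gv = genomes[i];
    std::vector<int> codons(gv.begin(), gv.end());
    int nn; bool valid;
    fit[i] = evaluate_genome(codons, g, max_wraps, X, y, stack, out, tokens, nn, valid);
    if (!valid) fit[i] = 0.0;
  }
  return fit;
}

// Evolve one deme for n_generations. Returns the final population, its
// fitness, and a per-generation log of the deme's best (fitness, node count,
// tokens). Selection: tournament; variation: single-point crossover with cut
// points chosen independently per parent, then per-codon uniform mutation.
// [[Rcpp::export]]
List cpp_evolve_deme(List genomes, NumericMatrix X, IntegerVector y, List enc,
                     int n_generations, double p_crossover, double p_mutation,
                     int tournament_size, int elitism, int max_wraps,
                     int max_genome_length, double seed) {
  GrammarEnc g = build_enc(enc);
  Pcg32 rng((uint64_t)seed);
  const int np = genomes.size();
  std::vector<std::vector<int> > pop(np), nextpop(np);
  std::vector<double> fit(np), nextfit(np);
  std::vector<int> nodes(np), nextnodes(np);
  std::vector<std::vector<int> > toks(np), nexttoks(np);

  std::vector<std::vector<double> > stack;
  std::vector<double> out;

  for (int i = 0; i < np; ++i) {
    IntegerVector gv = genomes[i];
    pop[i].assign(gv.begin(), gv.end());
    bool valid;
    fit[i] = evaluate_genome(pop[i], g, max_wraps, X, y, stack, out,
                             toks[i], nodes[i], valid);
  }

  List log(n_generations);

  for (int gen = 0; gen < n_generations; ++gen) {
    // elite: the `elitism` best individuals copied unchanged (stable order)
    int n_elite = std::min(elitism, np);
    std::vector<int> order(np);
    for (int i = 0; i < np; ++i) order[i] = i;
    std::partial_sort(order.begin(), order.begin() + n_elite, order.end(),
                      [&](int a, int b) {
                        return fit[a] > fit[b] || (fit[a] == fit[b] && a < b);
                      });
    int filled = 0;
    for (int e = 0; e < n_elite; ++e, ++filled) {
      int b = order[e];
      nextpop[filled] = pop[b];
      nextfit[filled] = fit[b];
      nextnodes[filled] = nodes[b];
      nexttoks[filled] = toks[b];
    }
    while (filled < np) {
      // tournament selection of two parents
      int pa = rng.below(np), pb = rng.below(np);
      for (int t = 1; t < tournament_size; ++t) {
        int c = rng.below(np);
        if (fit[c] > fit[pa]) pa = c;
        c = rng.below(np);
        if (fit[c] > fit[pb]) pb = c;
      }
      std::vector<int> child;
      if (rng.runif01() < p_crossover) {
        const std::vector<int> &A = pop[pa], &B = pop[pb];
        int ca = 1 + rng.below((int)A.size());
        int cb = rng.below((int)B.size() + 1);
        child.assign(A.begin(), A.begin() + ca);
        child.insert(child.end(), B.begin() + cb, B.end());
        if ((int)child.size() > max_genome_length)
          child.resize(max_genome_length);
      } else {
        child = pop[pa];
      }
      mutate_codons(child, p_mutation, rng);
      bool valid;
      nextfit[filled] = evaluate_genome(child, g, max_wraps, X, y, stack, out,
                                        nexttoks[filled], nextnodes[filled], valid);
      nextpop[filled] = child;
      ++filled;
    }
    pop.swap(nextpop);
    fit.swap(nextfit);
    nodes.swap(nextnodes);
    toks.swap(nexttoks);

    int b = 0;
    for (int i = 1; i < np; ++i) if (fit[i] > fit[b]) b = i;
    log[gen] = List::create(
      _["fitness"] = fit[b],
      _["nodes"] = nodes[b],
      _["tokens"] = IntegerVector(toks[b].begin(), toks[b].end()));
  }

  List out_genomes(np);
  NumericVector out_fit(np);
  for (int i = 0; i < np; ++i) {
    out_genomes[i] = IntegerVector(pop[i].begin(), pop[i].end());
    out_fit[i] = fit[i];
  }
  return List::create(_["genomes"] = out_genomes,
                      _["fitness"] = out_fit,
                      _["log"] = log);
}
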