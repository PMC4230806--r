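// Square-free GF(2) polynomial arithmetic in the Boolean quotient ring,
// Buchberger's algorithm under lexicographic order, and solution
// enumeration by back-substitution with branching.
//
// A monomial is a strictly increasing vector of variable ranks (rank 1 =
// highest lex variable); the empty monomial is the constant 1. A polynomial
// is a vector of distinct monomials sorted in decreasing lex order; the
// empty vector is the zero polynomial. Addition is symmetric difference
// (coefficients mod 2); multiplication joins variable sets (exponents
// truncated to 1, i.e. the field relations x^2 = x are built in).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <deque>
#include <queue>
using namespace Rcpp;

typedef std::vector<int> Mono;
typedef std::vector<Mono> Poly;

// lex order: is a > b?
static bool mono_gt(const Mono &a, const Mono &b) {
  size_t i = 0;
  while (i < a.size() && i < b.size()) {
    if (a[i] != b[i]) return a[i] < b[i]; // smaller rank = higher variable
    ++i;
  }
  return a.size() > b.size();
}

static bool mono_eq(const Mono &a, const Mono &b) { return a == b; }

// canonicalize an arbitrary bag of monomials: sort desc, cancel equal pairs
static Poly canon(std::vector<Mono> bag) {
  std::sort(bag.begin(), bag.end(), mono_gt);
  Poly out;
  size_t i = 0;
  while (i < bag.size()) {
    size_t j = i + 1;
    while (j < bag.size() && mono_eq(bag[i], bag[j])) ++j;
    if ((j - i) % 2 == 1) out.push_back(bag[i]);
    i = j;
  }
  return out;
}

// p + q, both canonical: linear merge keeping symmetric difference
static Poly add(const Poly &p, const Poly &q) {
  Poly out;
  out.reserve(p.size() + q.size());
  size_t i = 0, j = 0;
  while (i < p.size() && j < q.size()) {
    if (mono_eq(p[i], q[j])) { ++i; ++j; }
    else if (mono_gt(p[i], q[j])) out.push_back(p[i++]);
    else out.push_back(q[j++]);
  }
  while (i < p.size()) out.push_back(p[i++]);
  while (j < q.size()) out.push_back(q[j++]);
  return out;
}

// p * m for a single monomial m (set union per monomial, then cancel)
static Poly mul_mono(const Poly &p, const Mono &m) {
  if (m.empty() || p.empty()) return p;
  std::vector<Mono> bag;
  bag.reserve(p.size());
  for (const Mono &x : p) {
    Mono u;
    u.reserve(x.size() + m.size());
    std::set_union(x.begin(), x.end(), m.begin(), m.end(), std::back_inserter(u));
    bag.push_back(std::move(u));
  }
  return canon(std::move(bag));
}

static bool divides(const Mono &d, const Mono &m) {
  return std::includes(m.begin(), m.end(), d.begin(), d.end());
}

static Mono quotient(const Mono &m, const Mono &d) {
  Mono q;
  std::set_difference(m.begin(), m.end(), d.begin(), d.end(), std::back_inserter(q));
  return q;
}

static bool is_one(const Poly &p) { return p.size() == 1 && p[0].empty(); }

// Work budget for the basis computation. Lex elimination can suffer
// exponential intermediate swell on dense inputs even when the final basis
// is small; when the budget runs out the caller falls back to enumerating
// on the inter-reduced input system, which is equally exact.
struct BudgetExceeded {};
struct Budget {
  long long left;
  explicit Budget(long long n) : left(n) {}
  void spend(long long n) {
    left -= n;
    if (left < 0) throw BudgetExceeded();
  }
};

// full normal form of p modulo basis (leading and tail monomials reduced)
static Poly normal_form(Poly p, const std::vector<Poly> &G, Budget &budget) {
  size_t i = 0;
  while (i < p.size()) {
    const Mono &m = p[i];
    int hit = -1;
    for (size_t j = 0; j < G.size(); ++j) {
      if (G[j][0].size() <= m.size() && divides(G[j][0], m)) { hit = (int)j; break; }
    }
    if (hit < 0) { ++i; continue; }
    Mono cof = quotient(m, G[hit][0]);
    budget.spend((long long)p.size() + (long long)G[hit].size());
    p = add(p, mul_mono(G[hit], cof));
    // monomials before position i are larger than m and unaffected
  }
  return p;
}

// Buchberger in the Boolean quotient ring. Besides the usual pairwise
// S-polynomials (square-free lcm), every element f = m + r contributes, for
// each variable x in its leading monomial m, the S-polynomial against the
// field relation x^2 + x, which simplifies to x*r + m. No coprimality
// pruning (the product criterion is not valid in the quotient ring).
struct Pair {
  Mono lcm;      // selection key: degree, then lex-ascending
  int i, j;      // j == -1 marks the field pair of element i
};

struct PairWorse { // priority queue: smallest (degree, lex) lcm on top
  bool operator()(const Pair &a, const Pair &b) const {
    if (a.lcm.size() != b.lcm.size()) return a.lcm.size() > b.lcm.size();
    return mono_gt(a.lcm, b.lcm);
  }
};

// Computes the reduced Groebner basis; if the work budget runs out,
// returns the partial basis accumulated so far (every element lies in the
// ideal, so the solution set is unchanged -- only pruning power is lost)
// and sets *complete = false.
static std::vector<Poly> buchberger(std::vector<Poly> G, Budget &budget,
                                    bool *complete) {
  if (complete) *complete = true;
  // drop zeros and exact duplicates
  {
    std::vector<Poly> u;
    for (Poly &p : G) {
      if (p.empty()) continue;
      bool dup = false;
      for (const Poly &q : u) if (q == p) { dup = true; break; }
      if (!dup) u.push_back(std::move(p));
    }
    G = std::move(u);
  }
  try {
  // inter-reduce the input once: smaller starting polynomials
  for (size_t i = 0; i < G.size(); ++i) {
    std::vector<Poly> others;
    for (size_t j = 0; j < G.size(); ++j) if (j != i && !G[j].empty()) others.push_back(G[j]);
    G[i] = normal_form(G[i], others, budget);
  }
  {
    std::vector<Poly> u;
    for (Poly &p : G) if (!p.empty()) u.push_back(std::move(p));
    G = std::move(u);
  }
  std::priority_queue<Pair, std::vector<Pair>, PairWorse> pairs;
  auto push_pairs = [&](int k) {
    const Mono &ltk = G[k][0];
    for (int i = 0; i < k; ++i) {
      Pair p;
      std::set_union(G[i][0].begin(), G[i][0].end(), ltk.begin(), ltk.end(),
                     std::back_inserter(p.lcm));
      p.i = i; p.j = k;
      pairs.push(std::move(p));
    }
    Pair fp;            // field pair: S against x^2 + x for x | LT
    fp.lcm = ltk;       // its lcm is LT(f) * x, same square-free support
    fp.i = k; fp.j = -1;
    pairs.push(std::move(fp));
  };
  for (size_t k = 0; k < G.size(); ++k) push_pairs((int)k);

  while (!pairs.empty()) {
    Rcpp::checkUserInterrupt();
    Pair pr = pairs.top();
    pairs.pop();
    std::vector<Poly> cands;
    if (pr.j < 0) {
      const Poly &f = G[pr.i];
      const Mono &m = f[0];
      Poly tail(f.begin() + 1, f.end());
      for (int x : m) {
        Mono mx(1, x);
        Poly s = mul_mono(tail, mx);
        Poly lead(1, m);
        s = add(s, lead);
        cands.push_back(std::move(s));
      }
    } else {
      const Poly &f = G[pr.i];
      const Poly &g = G[pr.j];
      Poly s = add(mul_mono(f, quotient(pr.lcm, f[0])),
                   mul_mono(g, quotient(pr.lcm, g[0])));
      cands.push_back(std::move(s));
    }
    for (Poly &s : cands) {
      Poly h = normal_form(std::move(s), G, budget);
      if (h.empty()) continue;
      int k = (int)G.size();
      G.push_back(h);
      push_pairs(k);
      if (is_one(h)) {
        std::vector<Poly> one(1, G[k]);
        return one;
      }
    }
  }
  // minimalize: drop elements whose LT is divisible by another's LT
  std::vector<bool> keep(G.size(), true);
  for (size_t i = 0; i < G.size(); ++i) {
    for (size_t j = 0; j < G.size(); ++j) {
      if (i == j || !keep[j]) continue;
      if (G[j][0].size() < G[i][0].size() ||
          (G[j][0].size() == G[i][0].size() && j < i)) {
        if (divides(G[j][0], G[i][0])) { keep[i] = false; break; }
      }
    }
  }
  std::vector<Poly> M;
  for (size_t i = 0; i < G.size(); ++i) if (keep[i]) M.push_back(G[i]);
  // inter-reduce tails
  for (size_t i = 0; i < M.size(); ++i) {
    std::vector<Poly> others;
    for (size_t j = 0; j < M.size(); ++j) if (j != i) others.push_back(M[j]);
    M[i] = normal_form(M[i], others, budget);
  }
  std::vector<Poly> out;
  for (Poly &p : M) if (!p.empty()) out.push_back(std::move(p));
  std::sort(out.begin(), out.end(),
            [](const Poly &a, const Poly &b) { return mono_gt(a[0], b[0]); });
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
  } catch (BudgetExceeded &) {
    if (complete) *complete = false;
    std::vector<Poly> partial;
    for (Poly &p : G) if (!p.empty()) partial.push_back(std::move(p));
    return partial;
  }
}

static Poly poly_from_sexp(List lp) {
  std::vector<Mono> bag;
  for (int i = 0; i < lp.size(); ++i) {
    IntegerVector v = lp[i];
    Mono m(v.begin(), v.end());
    std::sort(m.begin(), m.end());
    m.erase(std::unique(m.begin(), m.end()), m.end());
    bag.push_back(std::move(m));
  }
  return canon(std::move(bag));
}

static List poly_to_sexp(const Poly &p) {
  List out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = IntegerVector(p[i].begin(), p[i].end());
  return out;
}

// [[Rcpp::export(name = ".gb_cpp")]]
List gb_cpp(List polys) {
  std::vector<Poly> G;
  for (int i = 0; i < polys.size(); ++i) G.push_back(poly_from_sexp(polys[i]));
  Budget budget(4000000000LL);
  bool complete = true;
  std::vector<Poly> B = buchberger(std::move(G), budget, &complete);
  if (!complete) {
    Rcpp::stop("Groebner basis computation exceeded its work budget (dense system)");
  }
  List out(B.size());
  for (size_t i = 0; i < B.size(); ++i) out[i] = poly_to_sexp(B[i]);
  return out;
}

// substitute rank -> value; returns canonical polynomial
static Poly subst(const Poly &p, int r, int val) {
  std::vector<Mono> bag;
  bag.reserve(p.size());
  bool touched = false;
  for (const Mono &m : p) {
    if (std::binary_search(m.begin(), m.end(), r)) {
      touched = true;
      if (val == 1) {
        Mono q;
        q.reserve(m.size() - 1);
        for (int x : m) if (x != r) q.push_back(x);
        bag.push_back(std::move(q));
      } // val == 0: monomial vanishes
    } else {
      bag.push_back(m);
    }
  }
  if (!touched) return p;
  return canon(std::move(bag));
}

struct SolveState {
  std::vector<int> branch_order; // ranks, lowest lex variable first
  long max_solutions;
  std::vector<std::vector<int> > sols; // assignments in branch order
  bool capped;
  long branches;
};

static void solve_rec(const std::vector<Poly> &polys, size_t depth,
                      std::vector<int> &assign, SolveState &st) {
  if (st.capped) return;
  for (const Poly &p : polys) if (is_one(p)) return; // contradiction
  if (depth == st.branch_order.size()) {
    st.sols.push_back(assign);
    if ((long)st.sols.size() > st.max_solutions) st.capped = true;
    return;
  }
  int r = st.branch_order[depth];
  for (int val = 0; val <= 1; ++val) {
    ++st.branches;
    if (st.branches % 4096 == 0) Rcpp::checkUserInterrupt();
    std::vector<Poly> nxt;
    nxt.reserve(polys.size());
    bool contradiction = false;
    for (const Poly &p : polys) {
      Poly q = subst(p, r, val);
      if (q.empty()) continue;
      if (is_one(q)) { contradiction = true; break; }
      nxt.push_back(std::move(q));
    }
    if (contradiction) continue;
    assign.push_back(val);
    solve_rec(nxt, depth + 1, assign, st);
    assign.pop_back();
    if (st.capped) return;
  }
}

// Solve one component: Groebner basis, then back-substitution from the
// lowest variable of the elimination order upward. `ranks` are the
// component's variable ranks in ascending order; the returned matrix has
// one column per rank in that order. Returns list(states=, gb_size=,
// capped=, branches=).
// [[Rcpp::export(name = ".solve_component_cpp")]]
List solve_component_cpp(List polys, IntegerVector ranks, double max_solutions) {
  std::vector<Poly> G;
  for (int i = 0; i < polys.size(); ++i) {
    Poly p = poly_from_sexp(polys[i]);
    if (!p.empty()) G.push_back(std::move(p));
  }
  // Prefer the reduced basis (best pruning); on dense systems whose lex
  // elimination swells past the work budget, enumerate on the canonical
  // input system instead -- the branch-and-substitute search is exact
  // either way, the basis only sharpens pruning.
  Budget budget(20000000LL);
  bool gb_ok = true;
  std::vector<Poly> B = buchberger(G, budget, &gb_ok);
  if (B.empty() && !G.empty()) B = G;  // defensive: never lose the system
  SolveState st;
  st.max_solutions = (long)max_solutions;
  st.capped = false;
  st.branches = 0;
  for (int i = ranks.size() - 1; i >= 0; --i) st.branch_order.push_back(ranks[i]);
  if (!(B.size() == 1 && is_one(B[0]))) {
    std::vector<int> assign;
    assign.reserve(ranks.size());
    solve_rec(B, 0, assign, st);
  }
  IntegerMatrix out((int)st.sols.size(), ranks.size());
  // branch order is reversed ranks; column j of `out` = ranks[j]
  for (size_t i = 0; i < st.sols.size(); ++i) {
    for (int j = 0; j < ranks.size(); ++j) {
      out((int)i, j) = st.sols[i][ranks.size() - 1 - j];
    }
  }
  return List::create(_["states"] = out,
                      _["gb_size"] = (int)B.size(),
                      _["gb_complete"] = gb_ok,
                      _["capped"] = st.capped,
                      _["branches"] = (double)st.branches);
}
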