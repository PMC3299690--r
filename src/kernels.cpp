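// Computational kernels: ordered-state (Wagner) Sankoff scoring, TBR branch
// swapping, Nussinov base-pair maximization, and local forest alignment.
// Trees are exchanged with R as 1-based edge matrices (parent, child); tips are
// numbered 1..ntip, internal nodes ntip+1..2*ntip-2 (unrooted binary, the
// "root" is the trifurcating internal node used to orient the edge matrix).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <sstream>
using namespace Rcpp;

static const int BIG = 100000000; // effectively infinite step count

typedef std::vector<std::vector<int> > Adj;

// min-plus convolution with |i-j| cost ("distance transform"), in place.
static void dtransform(std::vector<int>& g) {
    const int ns = (int) g.size();
    for (int i = 1; i < ns; ++i) g[i] = std::min(g[i], g[i - 1] + 1);
    for (int i = ns - 2; i >= 0; --i) g[i] = std::min(g[i], g[i + 1] + 1);
}

static Adj adj_from_edge(const IntegerMatrix& edge, int nnode) {
    Adj adj(nnode);
    for (int k = 0; k < edge.nrow(); ++k) {
        int a = edge(k, 0) - 1, b = edge(k, 1) - 1;
        adj[a].push_back(b);
        adj[b].push_back(a);
    }
    return adj;
}

// orientation of an (unrooted) adjacency from a chosen root: preorder + parents
static void orient(const Adj& adj, int root, std::vector<int>& order,
                   std::vector<int>& parent) {
    const int N = (int) adj.size();
    order.clear(); order.reserve(N);
    parent.assign(N, -1);
    std::vector<char> seen(N, 0);
    std::vector<int> stack;
    stack.push_back(root);
    seen[root] = 1;
    while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        order.push_back(u);
        for (size_t i = 0; i < adj[u].size(); ++i) {
            int v = adj[u][i];
            if (!seen[v]) { seen[v] = 1; parent[v] = u; stack.push_back(v); }
        }
    }
}

// first usable root: an internal node still carrying edges
static int pick_root(const Adj& adj, int ntip) {
    for (int x = ntip; x < (int) adj.size(); ++x)
        if (!adj[x].empty()) return x;
    return 0;
}

// Sankoff per-character minimal step counts on an oriented tree.
static void sankoff_chars(const Adj& adj, int root, int ntip,
                          const IntegerMatrix& tip_states, int ns,
                          std::vector<double>& out) {
    std::vector<int> order, parent;
    orient(adj, root, order, parent);
    const int N = (int) adj.size();
    const int M = (int) order.size();
    const int nchar = tip_states.ncol();
    out.assign(nchar, 0.0);
    std::vector<std::vector<int> > cost(N, std::vector<int>(ns));
    for (int c = 0; c < nchar; ++c) {
        for (int k = 0; k < M; ++k) {
            int u = order[k];
            if (u < ntip) {
                int s = tip_states(u, c);
                if (s == NA_INTEGER) {
                    std::fill(cost[u].begin(), cost[u].end(), 0);
                } else {
                    std::fill(cost[u].begin(), cost[u].end(), BIG);
                    cost[u][s] = 0;
                }
            } else {
                std::fill(cost[u].begin(), cost[u].end(), 0);
            }
        }
        // children precede parents in reversed preorder
        for (int k = M - 1; k >= 1; --k) {
            int u = order[k];
            std::vector<int> m = cost[u];
            dtransform(m);
            std::vector<int>& p = cost[parent[u]];
            for (int i = 0; i < ns; ++i) p[i] += m[i];
        }
        int best = BIG;
        for (int i = 0; i < ns; ++i) best = std::min(best, cost[root][i]);
        out[c] = best;
    }
}

static double score_weighted(const Adj& adj, int ntip,
                             const IntegerMatrix& tip_states, int ns,
                             const NumericVector& w) {
    int root = pick_root(adj, ntip);
    std::vector<double> pc;
    sankoff_chars(adj, root, ntip, tip_states, ns, pc);
    double total = 0;
    for (size_t c = 0; c < pc.size(); ++c) total += w[c] * pc[c];
    return total;
}

// [[Rcpp::export]]
NumericVector sankoff_per_char_cpp(IntegerMatrix edge, int ntip,
                                   IntegerMatrix tip_states, int ns) {
    int nnode = 0;
    for (int k = 0; k < edge.nrow(); ++k)
        nnode = std::max(nnode, std::max(edge(k, 0), edge(k, 1)));
    Adj adj = adj_from_edge(edge, nnode);
    int root = pick_root(adj, ntip);
    std::vector<double> pc;
    sankoff_chars(adj, root, ntip, tip_states, ns, pc);
    return wrap(pc);
}

// [[Rcpp::export]]
double score_edge_cpp(IntegerMatrix edge, int ntip, IntegerMatrix tip_states,
                      int ns, NumericVector w) {
    int nnode = 0;
    for (int k = 0; k < edge.nrow(); ++k)
        nnode = std::max(nnode, std::max(edge(k, 0), edge(k, 1)));
    Adj adj = adj_from_edge(edge, nnode);
    return score_weighted(adj, ntip, tip_states, ns, w);
}

// ---- adjacency surgery helpers ----

static int degree(const Adj& adj, int u) { return (int) adj[u].size(); }

static void rm_edge(Adj& adj, int u, int v) {
    adj[u].erase(std::find(adj[u].begin(), adj[u].end(), v));
    adj[v].erase(std::find(adj[v].begin(), adj[v].end(), u));
}

static void add_edge(Adj& adj, int u, int v) {
    adj[u].push_back(v);
    adj[v].push_back(u);
}

// remove a degree-2 node, fusing its two incident edges
static void suppress(Adj& adj, int u) {
    int a = adj[u][0], b = adj[u][1];
    rm_edge(adj, u, a);
    rm_edge(adj, u, b);
    add_edge(adj, a, b);
}

static void subdivide(Adj& adj, int x, int y, int mid) {
    rm_edge(adj, x, y);
    add_edge(adj, x, mid);
    add_edge(adj, mid, y);
}

static void component_edges(const Adj& adj, int start,
                            std::vector<std::pair<int, int> >& edges,
                            std::vector<int>& nodes) {
    std::vector<int> stack;
    std::vector<char> seen(adj.size(), 0);
    stack.push_back(start);
    seen[start] = 1;
    edges.clear(); nodes.clear();
    while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        nodes.push_back(u);
        for (size_t i = 0; i < adj[u].size(); ++i) {
            int v = adj[u][i];
            if (u < v) edges.push_back(std::make_pair(u, v));
            if (!seen[v]) { seen[v] = 1; stack.push_back(v); }
        }
    }
    std::sort(edges.begin(), edges.end());
}

static std::vector<std::pair<int, int> > all_edges(const Adj& adj) {
    std::vector<std::pair<int, int> > out;
    for (int u = 0; u < (int) adj.size(); ++u)
        for (size_t i = 0; i < adj[u].size(); ++i)
            if (u < adj[u][i]) out.push_back(std::make_pair(u, adj[u][i]));
    std::sort(out.begin(), out.end());
    return out;
}

// canonical topology key: per internal edge, the sorted tip set not containing
// tip 0; keys sorted and concatenated
static std::string topo_key(const Adj& adj, int ntip) {
    std::vector<std::pair<int, int> > edges = all_edges(adj);
    std::vector<std::string> parts;
    for (size_t e = 0; e < edges.size(); ++e) {
        int u = edges[e].first, v = edges[e].second;
        if (u < ntip || v < ntip) continue; // pendant edges are trivial splits
        // tips on v's side of edge (u,v)
        std::vector<int> stack; stack.push_back(v);
        std::vector<char> seen(adj.size(), 0);
        seen[u] = 1; seen[v] = 1;
        std::vector<int> tips;
        while (!stack.empty()) {
            int x = stack.back(); stack.pop_back();
            if (x < ntip) tips.push_back(x);
            for (size_t i = 0; i < adj[x].size(); ++i)
                if (!seen[adj[x][i]]) { seen[adj[x][i]] = 1; stack.push_back(adj[x][i]); }
        }
        std::sort(tips.begin(), tips.end());
        bool has0 = !tips.empty() && tips[0] == 0;
        if (has0) { // complement
            std::vector<int> comp;
            size_t j = 0;
            for (int t = 0; t < ntip; ++t) {
                if (j < tips.size() && tips[j] == t) { ++j; continue; }
                comp.push_back(t);
            }
            tips.swap(comp);
        }
        std::ostringstream os;
        for (size_t i = 0; i < tips.size(); ++i) os << tips[i] << ",";
        parts.push_back(os.str());
    }
    std::sort(parts.begin(), parts.end());
    std::string key;
    for (size_t i = 0; i < parts.size(); ++i) { key += parts[i]; key += "|"; }
    return key;
}

static IntegerMatrix adj_to_edge(const Adj& adj, int ntip) {
    int root = pick_root(adj, ntip);
    std::vector<int> order, parent;
    orient(adj, root, order, parent);
    IntegerMatrix edge((int) order.size() - 1, 2);
    int r = 0;
    for (size_t k = 1; k < order.size(); ++k) {
        edge(r, 0) = parent[order[k]] + 1;
        edge(r, 1) = order[k] + 1;
        ++r;
    }
    return edge;
}

// Enumerate TBR candidates of the current tree; callback via functor pattern
// is avoided for simplicity: one routine either searches for the first
// improvement or collects ties at the current best length.
struct TbrResult {
    bool improved;
    Adj adj;
    double len;
};

static TbrResult tbr_pass(const Adj& adj0, int ntip,
                          const IntegerMatrix& tip_states, int ns,
                          const NumericVector& w, double cur_len,
                          bool collect, double eps,
                          std::vector<Adj>* ties, int max_trees,
                          std::vector<std::string>* keys) {
    TbrResult res; res.improved = false; res.len = cur_len;
    std::vector<std::pair<int, int> > edges = all_edges(adj0);
    for (size_t e = 0; e < edges.size(); ++e) {
        int u = edges[e].first, v = edges[e].second;
        Adj base = adj0;
        rm_edge(base, u, v);
        // component membership while u and v still anchor their own sides
        std::vector<std::pair<int, int> > edgesA, edgesB;
        std::vector<int> nodesA, nodesB;
        if (degree(base, u) == 0) nodesA.assign(1, u);
        else component_edges(base, u, edgesA, nodesA);
        if (degree(base, v) == 0) nodesB.assign(1, v);
        else component_edges(base, v, edgesB, nodesB);
        // suppress endpoints left with degree 2, remember the freed node ids
        std::vector<int> freed;
        if (degree(base, u) == 2) { suppress(base, u); freed.push_back(u); }
        if (degree(base, v) == 2) { suppress(base, v); freed.push_back(v); }
        // refresh edge lists after suppression (anchors: any connected member)
        if (nodesA.size() > 1) {
            int anchor = -1;
            for (size_t i = 0; i < nodesA.size(); ++i)
                if (degree(base, nodesA[i]) > 0) { anchor = nodesA[i]; break; }
            std::vector<int> tmp;
            component_edges(base, anchor, edgesA, tmp);
        }
        if (nodesB.size() > 1) {
            int anchor = -1;
            for (size_t i = 0; i < nodesB.size(); ++i)
                if (degree(base, nodesB[i]) > 0) { anchor = nodesB[i]; break; }
            std::vector<int> tmp;
            component_edges(base, anchor, edgesB, tmp);
        }
        bool tipA = edgesA.empty(); // single-tip component
        bool tipB = edgesB.empty();
        if (tipA && tipB) continue;  // 2-taxon tree, nothing to do
        std::vector<std::pair<int, int> > listA = tipA
            ? std::vector<std::pair<int, int> >(1, std::make_pair(-1, -1)) : edgesA;
        std::vector<std::pair<int, int> > listB = tipB
            ? std::vector<std::pair<int, int> >(1, std::make_pair(-1, -1)) : edgesB;
        for (size_t ia = 0; ia < listA.size(); ++ia) {
            for (size_t ib = 0; ib < listB.size(); ++ib) {
                Adj cand = base;
                int endA, endB, fi = 0;
                if (tipA) endA = u; else {
                    subdivide(cand, listA[ia].first, listA[ia].second, freed[fi]);
                    endA = freed[fi]; ++fi;
                }
                if (tipB) endB = v; else {
                    subdivide(cand, listB[ib].first, listB[ib].second, freed[fi]);
                    endB = freed[fi]; ++fi;
                }
                add_edge(cand, endA, endB);
                double len = score_weighted(cand, ntip, tip_states, ns, w);
                if (!collect) {
                    if (len < cur_len - eps) {
                        res.improved = true;
                        res.adj = cand;
                        res.len = len;
                        return res;
                    }
                } else if (len <= cur_len + eps && (int) ties->size() < max_trees) {
                    std::string k = topo_key(cand, ntip);
                    if (std::find(keys->begin(), keys->end(), k) == keys->end()) {
                        keys->push_back(k);
                        ties->push_back(cand);
                    }
                }
            }
        }
    }
    return res;
}

// [[Rcpp::export]]
List tbr_search_cpp(IntegerMatrix edge, int ntip, IntegerMatrix tip_states,
                    int ns, NumericVector w, int max_trees, int max_iter) {
    int nnode = 0;
    for (int k = 0; k < edge.nrow(); ++k)
        nnode = std::max(nnode, std::max(edge(k, 0), edge(k, 1)));
    Adj adj = adj_from_edge(edge, nnode);
    // a rooted input carries a degree-2 root: unroot it
    for (int x = ntip; x < nnode; ++x)
        if (degree(adj, x) == 2) suppress(adj, x);
    double len = score_weighted(adj, ntip, tip_states, ns, w);
    const double eps = 1e-9;
    int it = 0;
    while (it++ < max_iter) {
        TbrResult r = tbr_pass(adj, ntip, tip_states, ns, w, len, false, eps,
                               0, 0, 0);
        if (!r.improved) break;
        adj = r.adj;
        len = r.len;
    }
    // collect equally parsimonious neighbours (plus the optimum itself)
    std::vector<Adj> ties;
    std::vector<std::string> keys;
    keys.push_back(topo_key(adj, ntip));
    ties.push_back(adj);
    if (ntip >= 4 && max_trees > 1)
        tbr_pass(adj, ntip, tip_states, ns, w, len, true, eps, &ties,
                 max_trees, &keys);
    List trees(ties.size());
    for (size_t i = 0; i < ties.size(); ++i)
        trees[i] = adj_to_edge(ties[i], ntip);
    return List::create(_["length"] = len, _["trees"] = trees,
                        _["iterations"] = it);
}

// ---- Nussinov base-pair maximization ----

static bool pairable(int a, int b) {
    // codes: 0=A 1=C 2=G 3=U, anything else unpairable
    if (a > b) std::swap(a, b);
    return (a == 0 && b == 3) || (a == 1 && b == 2) || (a == 2 && b == 3);
}

// [[Rcpp::export]]
IntegerVector nussinov_cpp(IntegerVector seq, int min_loop) {
    const int n = seq.size();
    IntegerVector partner(n, 0);
    if (n == 0) return partner;
    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = M[i][j - 1];
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!pairable(seq[k], seq[j])) continue;
                int sc = 1 + (k > i ? M[i][k - 1] : 0)
                           + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
                if (sc > best) best = sc;
            }
            M[i][j] = best;
        }
    }
    // traceback: prefer pairing j with the leftmost optimal k
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        bool done = false;
        for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
            if (!pairable(seq[k], seq[j])) continue;
            int sc = 1 + (k > i ? M[i][k - 1] : 0)
                       + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
            if (sc == M[i][j]) {
                partner[k] = j + 1;
                partner[j] = k + 1;
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
                done = true;
            }
        }
        if (!done) stack.push_back(std::make_pair(i, j - 1));
    }
    return partner;
}

// ---- local forest alignment ----
// Forest nodes arrive in preorder (parents before children, siblings 5'->3');
// parent[i] = 0 for top-level trees, else 1-based index of the parent.
// kind: 1 = P (paired), 0 = B (unpaired base).

struct Forest {
    int n;
    std::vector<int> kind;
    std::vector<std::vector<int> > kids; // ordered
    std::vector<int> roots;
    std::vector<int> size;
};

static Forest build_forest(const IntegerVector& kind,
                           const IntegerVector& parent) {
    Forest f;
    f.n = kind.size();
    f.kind.assign(kind.begin(), kind.end());
    f.kids.assign(f.n, std::vector<int>());
    for (int i = 0; i < f.n; ++i) {
        if (parent[i] == 0) f.roots.push_back(i);
        else f.kids[parent[i] - 1].push_back(i);
    }
    f.size.assign(f.n, 1);
    for (int i = f.n - 1; i >= 0; --i)
        for (size_t k = 0; k < f.kids[i].size(); ++k)
            f.size[i] += f.size[f.kids[i][k]];
    return f;
}

static const double NEG = -1e15;

// global alignment of two ordered subtree sequences given the subtree-pair
// similarity table S; deleting a subtree costs gap * its node count
static double align_global(const std::vector<int>& A, const std::vector<int>& B,
                           const Forest& f1, const Forest& f2,
                           const std::vector<std::vector<double> >& S,
                           double gap) {
    const int n = (int) A.size(), m = (int) B.size();
    std::vector<std::vector<double> > D(n + 1, std::vector<double>(m + 1, 0));
    for (int i = 1; i <= n; ++i) D[i][0] = D[i - 1][0] + gap * f1.size[A[i - 1]];
    for (int j = 1; j <= m; ++j) D[0][j] = D[0][j - 1] + gap * f2.size[B[j - 1]];
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double d = D[i - 1][j - 1] + S[A[i - 1]][B[j - 1]];
            double u = D[i - 1][j] + gap * f1.size[A[i - 1]];
            double l = D[i][j - 1] + gap * f2.size[B[j - 1]];
            D[i][j] = std::max(d, std::max(u, l));
        }
    }
    return D[n][m];
}

// Smith-Waterman over two subtree sequences, floored at 0; returns best cell
static double align_local_seq(const std::vector<int>& A,
                              const std::vector<int>& B,
                              const Forest& f1, const Forest& f2,
                              const std::vector<std::vector<double> >& S,
                              double gap) {
    const int n = (int) A.size(), m = (int) B.size();
    std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, 0));
    double best = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double d = H[i - 1][j - 1] + S[A[i - 1]][B[j - 1]];
            double u = H[i - 1][j] + gap * f1.size[A[i - 1]];
            double l = H[i][j - 1] + gap * f2.size[B[j - 1]];
            double h = std::max(0.0, std::max(d, std::max(u, l)));
            H[i][j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// [[Rcpp::export]]
double forest_align_cpp(IntegerVector kind1, IntegerVector parent1,
                        IntegerVector kind2, IntegerVector parent2,
                        double wp, double wb, double gap) {
    Forest f1 = build_forest(kind1, parent1);
    Forest f2 = build_forest(kind2, parent2);
    if (f1.n == 0 || f2.n == 0) return 0.0;
    // subtree-pair similarities, children (higher indices) first
    std::vector<std::vector<double> > S(f1.n, std::vector<double>(f2.n, NEG));
    for (int i = f1.n - 1; i >= 0; --i) {
        for (int j = f2.n - 1; j >= 0; --j) {
            if (f1.kind[i] != f2.kind[j]) { S[i][j] = NEG; continue; }
            double match = f1.kind[i] == 1 ? wp : wb;
            S[i][j] = match + align_global(f1.kids[i], f2.kids[j], f1, f2, S, gap);
        }
    }
    // local optimum over every pair of closed subforests: sibling windows
    // under every node pair (virtual roots included)
    double best = 0;
    std::vector<const std::vector<int>*> lists1, lists2;
    lists1.push_back(&f1.roots);
    for (int i = 0; i < f1.n; ++i)
        if (!f1.kids[i].empty()) lists1.push_back(&f1.kids[i]);
    lists2.push_back(&f2.roots);
    for (int j = 0; j < f2.n; ++j)
        if (!f2.kids[j].empty()) lists2.push_back(&f2.kids[j]);
    for (size_t a = 0; a < lists1.size(); ++a)
        for (size_t b = 0; b < lists2.size(); ++b)
            best = std::max(best, align_local_seq(*lists1[a], *lists2[b],
                                                  f1, f2, S, gap));
    return best;
}
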