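#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulation of independent genealogies under a
// demographic scenario made of constant-size populations, population splits
// (backward-in-time merges) and instantaneous admixture pulses.
//
// Conventions shared with the R wrappers:
//  * time is measured backward in generations, 0 = sampling time;
//  * Ne is the diploid effective size, so a pair of lineages in a
//    population coalesces at rate 1/(2*Ne) per generation;
//  * events come pre-sorted by (time, type) with pulses (type 0) applied
//    before merges (type 1) at equal times;
//  * event rows are (time, type, a, b, alpha): pulse moves each lineage of
//    recipient a to donor b with probability alpha; merge moves all
//    lineages of derived population a into ancestral population b.

struct Workspace {
    std::vector< std::vector<int> > act; // active lineages per population
    std::vector<int> parent;             // parent node of each node (-1 root)
    std::vector<double> ntime;           // node times (generations)
};

static void sim_genealogy(int n, int npop,
                          const std::vector<int> &nsam,
                          const std::vector<double> &two_ne,
                          const NumericMatrix &ev,
                          Workspace &w)
{
    const int nn = 2 * n - 1;
    w.parent.assign(nn, -1);
    w.ntime.assign(nn, 0.0);
    for (int p = 0; p < npop; ++p) w.act[p].clear();
    int id = 0;
    for (int p = 0; p < npop; ++p)
        for (int i = 0; i < nsam[p]; ++i) w.act[p].push_back(id++);

    int next_node = n, nlin = n, ei = 0;
    const int nev = ev.nrow();
    double t = 0.0;

    while (nlin > 1) {
        double tot = 0.0;
        for (int p = 0; p < npop; ++p) {
            const double k = (double) w.act[p].size();
            if (k > 1.0) tot += k * (k - 1.0) / 2.0 / two_ne[p];
        }
        const double tnext = (ei < nev) ? ev(ei, 0) : R_PosInf;
        const double dt = (tot > 0.0) ? exp_rand() / tot : R_PosInf;

        if (t + dt >= tnext) {
            if (!R_FINITE(tnext))
                stop("genealogy cannot coalesce: populations never share an ancestor");
            t = tnext;
            const int type = (int) ev(ei, 1);
            const int a = (int) ev(ei, 2) - 1;
            const int b = (int) ev(ei, 3) - 1;
            if (type == 0) {
                const double al = ev(ei, 4);
                std::vector<int> &A = w.act[a];
                size_t keep = 0;
                for (size_t i2 = 0; i2 < A.size(); ++i2) {
                    if (unif_rand() < al) w.act[b].push_back(A[i2]);
                    else A[keep++] = A[i2];
                }
                A.resize(keep);
            } else {
                for (size_t i2 = 0; i2 < w.act[a].size(); ++i2)
                    w.act[b].push_back(w.act[a][i2]);
                w.act[a].clear();
            }
            ++ei;
        } else {
            t += dt;
            // choose the population in which the coalescence happens
            double u = unif_rand() * tot, c = 0.0;
            int p = -1;
            for (int q = 0; q < npop; ++q) {
                const double k = (double) w.act[q].size();
                if (k > 1.0) {
                    p = q;
                    c += k * (k - 1.0) / 2.0 / two_ne[q];
                    if (u <= c) break;
                }
            }
            std::vector<int> &A = w.act[p];
            const int k = (int) A.size();
            int i1 = (int) (unif_rand() * k); if (i1 >= k) i1 = k - 1;
            int j1 = (int) (unif_rand() * (k - 1)); if (j1 >= k - 1) j1 = k - 2;
            if (j1 >= i1) ++j1;
            const int c1 = A[i1], c2 = A[j1];
            w.parent[c1] = next_node;
            w.parent[c2] = next_node;
            w.ntime[next_node] = t;
            A[i1] = next_node;
            A[j1] = A[k - 1];
            A.pop_back();
            ++next_node;
            --nlin;
        }
    }
}

// place one mutation uniformly on the genealogy; returns the node whose
// subtending branch carries it (every choice yields a segregating site
// because branches above the MRCA do not exist)
static int pick_branch(int n, const Workspace &w)
{
    const int nn = 2 * n - 1;
    double tot = 0.0;
    for (int i = 0; i < nn - 1; ++i) tot += w.ntime[w.parent[i]] - w.ntime[i];
    double u = unif_rand() * tot, c = 0.0;
    for (int i = 0; i < nn - 1; ++i) {
        c += w.ntime[w.parent[i]] - w.ntime[i];
        if (u <= c) return i;
    }
    return nn - 2;
}

// [[Rcpp::export(name = ".sim_sites_cpp")]]
IntegerMatrix sim_sites_cpp(IntegerVector nsam_, NumericVector ne_,
                            NumericMatrix events, int n_sites)
{
    const int npop = nsam_.size();
    std::vector<int> nsam(npop);
    std::vector<double> two_ne(npop);
    int n = 0;
    for (int p = 0; p < npop; ++p) {
        nsam[p] = nsam_[p];
        n += nsam_[p];
        two_ne[p] = 2.0 * ne_[p];
    }
    if (n < 2) stop("need at least two sampled haploid genomes");

    Workspace w;
    w.act.resize(npop);
    IntegerMatrix G(n_sites, n);

    for (int s = 0; s < n_sites; ++s) {
        sim_genealogy(n, npop, nsam, two_ne, events, w);
        const int v = pick_branch(n, w);
        for (int tip = 0; tip < n; ++tip) {
            int x = tip;
            while (x != -1) {
                if (x == v) { G(s, tip) = 1; break; }
                x = w.parent[x];
            }
        }
    }
    return G;
}

// [[Rcpp::export(name = ".sim_trees_cpp")]]
List sim_trees_cpp(IntegerVector nsam_, NumericVector ne_,
                   NumericMatrix events, int n_trees)
{
    const int npop = nsam_.size();
    std::vector<int> nsam(npop);
    std::vector<double> two_ne(npop);
    int n = 0;
    for (int p = 0; p < npop; ++p) {
        nsam[p] = nsam_[p];
        n += nsam_[p];
        two_ne[p] = 2.0 * ne_[p];
    }
    if (n < 2) stop("need at least two sampled haploid genomes");

    Workspace w;
    w.act.resize(npop);
    List out(n_trees);
    for (int i = 0; i < n_trees; ++i) {
        sim_genealogy(n, npop, nsam, two_ne, events, w);
        out[i] = List::create(
            _["parent"] = IntegerVector(w.parent.begin(), w.parent.end()),
            _["time"]   = NumericVector(w.ntime.begin(), w.ntime.end()));
    }
    return out;
}
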