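// Minimal fast5-style HDF5 container reader/writer built directly on the
// HDF5 C library: one raw-signal dataset plus one compound event-table
// dataset under configurable group paths (a '*' path component matches the
// first child, as in Raw/Reads/*/Signal). Field I/O uses per-member compound
// types so on-disk layouts with extra or reordered fields still read.

#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>
#include <cstring>

namespace {

struct H5Quiet {
  H5Quiet() { H5Eset_auto2(H5E_DEFAULT, nullptr, nullptr); }
};
static H5Quiet quiet_;

std::vector<std::string> split_path(const std::string& p) {
  std::vector<std::string> out;
  std::string cur;
  for (char c : p) {
    if (c == '/') { if (!cur.empty()) out.push_back(cur); cur.clear(); }
    else cur += c;
  }
  if (!cur.empty()) out.push_back(cur);
  return out;
}

// Resolve a path with optional '*' components to the containing group of the
// final component; returns group id (caller closes) and sets leaf name.
hid_t resolve_parent(hid_t file, const std::string& path, std::string& leaf) {
  std::vector<std::string> comps = split_path(path);
  if (comps.empty()) Rcpp::stop("malformed container: empty dataset path");
  leaf = comps.back();
  comps.pop_back();
  hid_t cur = H5Gopen2(file, "/", H5P_DEFAULT);
  for (const std::string& c : comps) {
    std::string name = c;
    if (c == "*") {
      char buf[256];
      ssize_t n = H5Lget_name_by_idx(cur, ".", H5_INDEX_NAME, H5_ITER_INC, 0,
                                     buf, sizeof(buf), H5P_DEFAULT);
      if (n < 0) {
        H5Gclose(cur);
        Rcpp::stop("malformed container: no child group to match '*' in '%s'",
                   path.c_str());
      }
      name = buf;
    } else if (H5Lexists(cur, name.c_str(), H5P_DEFAULT) <= 0) {
      H5Gclose(cur);
      Rcpp::stop("malformed container: missing group '%s' (in path '%s')",
                 name.c_str(), path.c_str());
    }
    hid_t nxt = H5Gopen2(cur, name.c_str(), H5P_DEFAULT);
    H5Gclose(cur);
    if (nxt < 0)
      Rcpp::stop("malformed container: cannot open group '%s' (in path '%s')",
                 name.c_str(), path.c_str());
    cur = nxt;
  }
  return cur;
}

hid_t make_lcpl() {
  hid_t lcpl = H5Pcreate(H5P_LINK_CREATE);
  H5Pset_create_intermediate_group(lcpl, 1);
  return lcpl;
}

void write_string_scalar(hid_t file, const std::string& path, const std::string& value) {
  hid_t st = H5Tcopy(H5T_C_S1);
  H5Tset_size(st, value.size() + 1);
  hid_t sp = H5Screate(H5S_SCALAR);
  hid_t lcpl = make_lcpl();
  hid_t ds = H5Dcreate2(file, path.c_str(), st, sp, lcpl, H5P_DEFAULT, H5P_DEFAULT);
  if (ds < 0) Rcpp::stop("cannot create dataset '%s'", path.c_str());
  H5Dwrite(ds, st, H5S_ALL, H5S_ALL, H5P_DEFAULT, value.c_str());
  H5Dclose(ds); H5Pclose(lcpl); H5Sclose(sp); H5Tclose(st);
}

}  // namespace

// [[Rcpp::export]]
bool cpp_h5_available() { return true; }

// [[Rcpp::export]]
void cpp_h5_write(std::string path, Rcpp::NumericVector signal,
                  Rcpp::List events, std::string fastq,
                  std::string signal_path, std::string events_path,
                  std::string fastq_path) {
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("cannot create HDF5 file '%s'", path.c_str());

  // signal
  hsize_t n = (hsize_t)signal.size();
  hid_t sp = H5Screate_simple(1, &n, nullptr);
  hid_t lcpl = make_lcpl();
  hid_t ds = H5Dcreate2(file, signal_path.c_str(), H5T_NATIVE_DOUBLE, sp, lcpl,
                        H5P_DEFAULT, H5P_DEFAULT);
  if (ds < 0) Rcpp::stop("cannot create dataset '%s'", signal_path.c_str());
  H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, signal.begin());
  H5Dclose(ds); H5Sclose(sp);

  // event table as a compound dataset
  Rcpp::NumericVector start = events["start"], length = events["length"],
                      mean = events["mean"], stdv = events["stdv"],
                      weight = events["weight"], pms = events["p_model_state"];
  Rcpp::IntegerVector move = events["move"];
  Rcpp::CharacterVector model_state = events["model_state"], base = events["base"];
  const hsize_t ne = (hsize_t)start.size();
  size_t klen = ne > 0 ? std::strlen(model_state[0]) : 5;

  hid_t str_k = H5Tcopy(H5T_C_S1); H5Tset_size(str_k, klen + 1);
  hid_t str_1 = H5Tcopy(H5T_C_S1); H5Tset_size(str_1, 2);
  size_t off = 0;
  struct Field { const char* name; hid_t type; size_t size; size_t off; };
  std::vector<Field> fs = {
    {"start", H5T_NATIVE_LLONG, 8, 0}, {"length", H5T_NATIVE_LLONG, 8, 0},
    {"mean", H5T_NATIVE_DOUBLE, 8, 0}, {"stdv", H5T_NATIVE_DOUBLE, 8, 0},
    {"model_state", str_k, klen + 1, 0}, {"move", H5T_NATIVE_INT, 4, 0},
    {"weight", H5T_NATIVE_DOUBLE, 8, 0}, {"p_model_state", H5T_NATIVE_DOUBLE, 8, 0},
    {"base", str_1, 2, 0}};
  for (auto& f : fs) { f.off = off; off += f.size; }
  hid_t ct = H5Tcreate(H5T_COMPOUND, off);
  for (auto& f : fs) H5Tinsert(ct, f.name, f.off, f.type);

  std::vector<char> buf(off * (ne > 0 ? ne : 1), 0);
  for (hsize_t i = 0; i < ne; ++i) {
    char* rec = buf.data() + i * off;
    long long v;
    v = (long long)start[i];  std::memcpy(rec + fs[0].off, &v, 8);
    v = (long long)length[i]; std::memcpy(rec + fs[1].off, &v, 8);
    double d;
    d = mean[i]; std::memcpy(rec + fs[2].off, &d, 8);
    d = stdv[i]; std::memcpy(rec + fs[3].off, &d, 8);
    std::strncpy(rec + fs[4].off, model_state[i], klen);
    int m = move[i]; std::memcpy(rec + fs[5].off, &m, 4);
    d = weight[i]; std::memcpy(rec + fs[6].off, &d, 8);
    d = pms[i]; std::memcpy(rec + fs[7].off, &d, 8);
    std::strncpy(rec + fs[8].off, base[i], 1);
  }
  hid_t esp = H5Screate_simple(1, &ne, nullptr);
  hid_t eds = H5Dcreate2(file, events_path.c_str(), ct, esp, lcpl, H5P_DEFAULT,
                         H5P_DEFAULT);
  if (eds < 0) Rcpp::stop("cannot create dataset '%s'", events_path.c_str());
  if (ne > 0) H5Dwrite(eds, ct, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
  H5Dclose(eds); H5Sclose(esp); H5Tclose(ct); H5Tclose(str_k); H5Tclose(str_1);

  if (!fastq.empty()) write_string_scalar(file, fastq_path, fastq);
  H5Pclose(lcpl);
  H5Fclose(file);
}

namespace {

hid_t open_dataset(hid_t file, const std::string& path) {
  std::string leaf;
  hid_t parent = resolve_parent(file, path, leaf);
  if (H5Lexists(parent, leaf.c_str(), H5P_DEFAULT) <= 0) {
    H5Gclose(parent);
    Rcpp::stop("malformed container: missing group '%s' (in path '%s')",
               leaf.c_str(), path.c_str());
  }
  hid_t ds = H5Dopen2(parent, leaf.c_str(), H5P_DEFAULT);
  H5Gclose(parent);
  if (ds < 0) Rcpp::stop("malformed container: cannot open '%s'", path.c_str());
  return ds;
}

// read a single member of a compound dataset into a typed vector
template <typename T>
std::vector<T> read_member_num(hid_t ds, hid_t ftype, const std::string& name,
                               hid_t mem_scalar, hsize_t n, bool& present) {
  std::vector<T> out(n);
  int idx = H5Tget_member_index(ftype, name.c_str());
  present = idx >= 0;
  if (!present) return out;
  hid_t mt = H5Tcreate(H5T_COMPOUND, sizeof(T));
  H5Tinsert(mt, name.c_str(), 0, mem_scalar);
  if (H5Dread(ds, mt, H5S_ALL, H5S_ALL, H5P_DEFAULT, out.data()) < 0)
    Rcpp::stop("failed reading event field '%s'", name.c_str());
  H5Tclose(mt);
  return out;
}

std::vector<std::string> read_member_str(hid_t ds, hid_t ftype, const std::string& name,
                                         hsize_t n, bool& present) {
  std::vector<std::string> out(n);
  int idx = H5Tget_member_index(ftype, name.c_str());
  present = idx >= 0;
  if (!present) return out;
  hid_t fmt = H5Tget_member_type(ftype, idx);
  size_t len = H5Tget_size(fmt);
  hid_t st = H5Tcopy(H5T_C_S1);
  H5Tset_size(st, len);
  hid_t mt = H5Tcreate(H5T_COMPOUND, len);
  H5Tinsert(mt, name.c_str(), 0, st);
  std::vector<char> buf(len * n, 0);
  if (H5Dread(ds, mt, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data()) < 0)
    Rcpp::stop("failed reading event field '%s'", name.c_str());
  for (hsize_t i = 0; i < n; ++i) {
    const char* p = buf.data() + i * len;
    out[i] = std::string(p, strnlen(p, len));
  }
  H5Tclose(mt); H5Tclose(st); H5Tclose(fmt);
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_h5_read(std::string path, std::string signal_path,
                       std::string events_path, std::string fastq_path) {
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("cannot open HDF5 file '%s'", path.c_str());

  hid_t ds = open_dataset(file, signal_path);
  hid_t sp = H5Dget_space(ds);
  hsize_t n = 0;
  H5Sget_simple_extent_dims(sp, &n, nullptr);
  Rcpp::NumericVector signal((R_xlen_t)n);
  if (n > 0)
    H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, signal.begin());
  H5Sclose(sp); H5Dclose(ds);

  hid_t eds = open_dataset(file, events_path);
  hid_t ftype = H5Dget_type(eds);
  hid_t esp = H5Dget_space(eds);
  hsize_t ne = 0;
  H5Sget_simple_extent_dims(esp, &ne, nullptr);
  bool ok, has_base;
  auto start = read_member_num<long long>(eds, ftype, "start", H5T_NATIVE_LLONG, ne, ok);
  if (!ok) Rcpp::stop("malformed container: event table lacks field 'start'");
  auto length = read_member_num<long long>(eds, ftype, "length", H5T_NATIVE_LLONG, ne, ok);
  if (!ok) Rcpp::stop("malformed container: event table lacks field 'length'");
  auto mean = read_member_num<double>(eds, ftype, "mean", H5T_NATIVE_DOUBLE, ne, ok);
  auto stdv = read_member_num<double>(eds, ftype, "stdv", H5T_NATIVE_DOUBLE, ne, ok);
  auto move = read_member_num<int>(eds, ftype, "move", H5T_NATIVE_INT, ne, ok);
  if (!ok) Rcpp::stop("malformed container: event table lacks field 'move'");
  auto weight = read_member_num<double>(eds, ftype, "weight", H5T_NATIVE_DOUBLE, ne, ok);
  auto pms = read_member_num<double>(eds, ftype, "p_model_state", H5T_NATIVE_DOUBLE, ne, ok);
  auto model_state = read_member_str(eds, ftype, "model_state", ne, ok);
  if (!ok) Rcpp::stop("malformed container: event table lacks field 'model_state'");
  auto base = read_member_str(eds, ftype, "base", ne, has_base);
  H5Sclose(esp); H5Tclose(ftype); H5Dclose(eds);

  // fastq is optional
  std::string fastq;
  bool has_fastq = false;
  {
    std::string leaf;
    try {
      hid_t parent = resolve_parent(file, fastq_path, leaf);
      if (H5Lexists(parent, leaf.c_str(), H5P_DEFAULT) > 0) {
        hid_t fds = H5Dopen2(parent, leaf.c_str(), H5P_DEFAULT);
        hid_t ft = H5Dget_type(fds);
        size_t len = H5Tget_size(ft);
        std::vector<char> buf(len + 1, 0);
        hid_t mt = H5Tcopy(H5T_C_S1);
        H5Tset_size(mt, len);
        H5Dread(fds, mt, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
        fastq = std::string(buf.data(), strnlen(buf.data(), len));
        has_fastq = true;
        H5Tclose(mt); H5Tclose(ft); H5Dclose(fds);
      }
      H5Gclose(parent);
    } catch (...) { /* optional path absent */ }
  }
  H5Fclose(file);

  Rcpp::NumericVector st((R_xlen_t)ne), le((R_xlen_t)ne);
  for (hsize_t i = 0; i < ne; ++i) { st[i] = (double)start[i]; le[i] = (double)length[i]; }
  Rcpp::List ev = Rcpp::List::create(
      Rcpp::Named("start") = st, Rcpp::Named("length") = le,
      Rcpp::Named("mean") = Rcpp::NumericVector(mean.begin(), mean.end()),
      Rcpp::Named("stdv") = Rcpp::NumericVector(stdv.begin(), stdv.end()),
      Rcpp::Named("model_state") = Rcpp::CharacterVector(model_state.begin(), model_state.end()),
      Rcpp::Named("move") = Rcpp::IntegerVector(move.begin(), move.end()),
      Rcpp::Named("weight") = Rcpp::NumericVector(weight.begin(), weight.end()),
      Rcpp::Named("p_model_state") = Rcpp::NumericVector(pms.begin(), pms.end()));
  return Rcpp::List::create(
      Rcpp::Named("signal") = signal, Rcpp::Named("events") = ev,
      Rcpp::Named("base") = has_base
          ? SEXP(Rcpp::CharacterVector(base.begin(), base.end()))
          : SEXP(R_NilValue),
      Rcpp::Named("fastq") = has_fastq ? SEXP(Rcpp::wrap(fastq)) : SEXP(R_NilValue));
}
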