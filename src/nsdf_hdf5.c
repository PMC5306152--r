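/* Minimal bridge to the HDF5 high-level Dimension Scales API and to
 * variable-length (ragged) double datasets, neither of which the rhdf5
 * high-level interface exposes.  Every function opens the file, does one
 * job and closes everything again, so these calls can be freely
 * interleaved with rhdf5 access as long as no rhdf5 handle is left open.
 */
#include <R.h>
#include <Rinternals.h>
#include "hdf5.h"
#include "hdf5_hl.h"

static hid_t open_file(SEXP file, unsigned flags)
{
    hid_t fid = H5Fopen(CHAR(STRING_ELT(file, 0)), flags, H5P_DEFAULT);
    if (fid < 0)
        error("cannot open HDF5 file '%s'", CHAR(STRING_ELT(file, 0)));
    return fid;
}

/* Mark `spath` as a named dimension scale and attach it to dimension
 * `idx` (C order, 0-based) of dataset `dpath`. */
SEXP C_h5ds_attach(SEXP file, SEXP dpath, SEXP spath, SEXP idx)
{
    hid_t fid = open_file(file, H5F_ACC_RDWR);
    hid_t did = H5Dopen2(fid, CHAR(STRING_ELT(dpath, 0)), H5P_DEFAULT);
    hid_t sid = H5Dopen2(fid, CHAR(STRING_ELT(spath, 0)), H5P_DEFAULT);
    herr_t st = -1;
    if (did >= 0 && sid >= 0) {
        const char *sp = CHAR(STRING_ELT(spath, 0));
        const char *base = strrchr(sp, '/');
        if (H5DSis_scale(sid) <= 0)
            H5DSset_scale(sid, base ? base + 1 : sp);
        st = H5DSattach_scale(did, sid, (unsigned) asInteger(idx));
    }
    if (did >= 0) H5Dclose(did);
    if (sid >= 0) H5Dclose(sid);
    H5Fclose(fid);
    return ScalarInteger((int) st);
}

/* Is `spath` attached as a scale to dimension `idx` of `dpath`?
 * Returns 1/0, or -1 if either dataset is missing. */
SEXP C_h5ds_is_attached(SEXP file, SEXP dpath, SEXP spath, SEXP idx)
{
    hid_t fid = open_file(file, H5F_ACC_RDONLY);
    int out = -1;
    htri_t dex = H5Lexists(fid, CHAR(STRING_ELT(dpath, 0)), H5P_DEFAULT);
    htri_t sex = H5Lexists(fid, CHAR(STRING_ELT(spath, 0)), H5P_DEFAULT);
    if (dex > 0 && sex > 0) {
        hid_t did = H5Dopen2(fid, CHAR(STRING_ELT(dpath, 0)), H5P_DEFAULT);
        hid_t sid = H5Dopen2(fid, CHAR(STRING_ELT(spath, 0)), H5P_DEFAULT);
        if (did >= 0 && sid >= 0) {
            htri_t st = H5DSis_attached(did, sid, (unsigned) asInteger(idx));
            out = st > 0 ? 1 : (st == 0 ? 0 : -1);
        }
        if (did >= 0) H5Dclose(did);
        if (sid >= 0) H5Dclose(sid);
    }
    H5Fclose(fid);
    return ScalarInteger(out);
}

SEXP C_h5ds_is_scale(SEXP file, SEXP spath)
{
    hid_t fid = open_file(file, H5F_ACC_RDONLY);
    int out = -1;
    if (H5Lexists(fid, CHAR(STRING_ELT(spath, 0)), H5P_DEFAULT) > 0) {
        hid_t sid = H5Dopen2(fid, CHAR(STRING_ELT(spath, 0)), H5P_DEFAULT);
        if (sid >= 0) {
            htri_t st = H5DSis_scale(sid);
            out = st > 0 ? 1 : (st == 0 ? 0 : -1);
            H5Dclose(sid);
        }
    }
    H5Fclose(fid);
    return ScalarInteger(out);
}

/* Detach a scale (used to build corrupted fixtures in tests). */
SEXP C_h5ds_detach(SEXP file, SEXP dpath, SEXP spath, SEXP idx)
{
    hid_t fid = open_file(file, H5F_ACC_RDWR);
    hid_t did = H5Dopen2(fid, CHAR(STRING_ELT(dpath, 0)), H5P_DEFAULT);
    hid_t sid = H5Dopen2(fid, CHAR(STRING_ELT(spath, 0)), H5P_DEFAULT);
    herr_t st = -1;
    if (did >= 0 && sid >= 0)
        st = H5DSdetach_scale(did, sid, (unsigned) asInteger(idx));
    if (did >= 0) H5Dclose(did);
    if (sid >= 0) H5Dclose(sid);
    H5Fclose(fid);
    return ScalarInteger((int) st);
}

/* Write a list of double vectors as a 1-D variable-length dataset
 * (one row per list element; empty rows allowed). */
SEXP C_h5vl_write(SEXP file, SEXP path, SEXP data)
{
    R_xlen_t n = XLENGTH(data);
    hvl_t *buf = (hvl_t *) R_alloc((size_t) (n > 0 ? n : 1), sizeof(hvl_t));
    for (R_xlen_t i = 0; i < n; i++) {
        SEXP el = VECTOR_ELT(data, i);
        buf[i].len = (size_t) XLENGTH(el);
        buf[i].p = XLENGTH(el) > 0 ? (void *) REAL(el) : NULL;
    }
    hid_t fid = open_file(file, H5F_ACC_RDWR);
    hid_t tid = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hsize_t dims[1] = { (hsize_t) n };
    hid_t spc = H5Screate_simple(1, dims, NULL);
    hid_t did = H5Dcreate2(fid, CHAR(STRING_ELT(path, 0)), tid, spc,
                           H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    herr_t st = -1;
    if (did >= 0) {
        st = H5Dwrite(did, tid, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);
        H5Dclose(did);
    }
    H5Sclose(spc);
    H5Tclose(tid);
    H5Fclose(fid);
    if (st < 0) error("failed to write variable-length dataset '%s'",
                      CHAR(STRING_ELT(path, 0)));
    return ScalarInteger(0);
}

/* Read a 1-D variable-length double dataset back as a list of vectors. */
SEXP C_h5vl_read(SEXP file, SEXP path)
{
    hid_t fid = open_file(file, H5F_ACC_RDONLY);
    hid_t did = H5Dopen2(fid, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    if (did < 0) {
        H5Fclose(fid);
        error("no such dataset '%s'", CHAR(STRING_ELT(path, 0)));
    }
    hid_t spc = H5Dget_space(did);
    hsize_t dims[1];
    H5Sget_simple_extent_dims(spc, dims, NULL);
    R_xlen_t n = (R_xlen_t) dims[0];
    hid_t tid = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hvl_t *buf = (hvl_t *) R_alloc((size_t) (n > 0 ? n : 1), sizeof(hvl_t));
    herr_t st = H5Dread(did, tid, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);
    SEXP out = PROTECT(allocVector(VECSXP, n));
    if (st >= 0) {
        for (R_xlen_t i = 0; i < n; i++) {
            R_xlen_t m = (R_xlen_t) buf[i].len;
            SEXP el = allocVector(REALSXP, m);
            SET_VECTOR_ELT(out, i, el);
            if (m > 0) memcpy(REAL(el), buf[i].p, (size_t) m * sizeof(double));
        }
        H5Dvlen_reclaim(tid, spc, H5P_DEFAULT, buf);
    }
    H5Tclose(tid);
    H5Sclose(spc);
    H5Dclose(did);
    H5Fclose(fid);
    if (st < 0) error("failed to read variable-length dataset '%s'",
                      CHAR(STRING_ELT(path, 0)));
    UNPROTECT(1);
    return out;
}
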