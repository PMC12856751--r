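# Session-time oracle (NOT a runtime dependency): computes reference tPBE
# pair-density-functional total energies from pyscf FCI RDMs, evaluating the
# PBE kernel through libxc at translated spin densities. Used once to freeze
# expected values into the R test suite.
import numpy as np
from pyscf import gto, scf, mcscf, fci, dft

def tpbe_energy(mol, mf, ncas, nelecas):
    mc = mcscf.CASCI(mf, ncas, nelecas)
    mc.kernel()
    ncore = mc.ncore
    casdm1, casdm2 = mc.fcisolver.make_rdm12(mc.ci, ncas, mc.nelecas)
    C = mc.mo_coeff
    Ccore = C[:, :ncore]; Cact = C[:, ncore:ncore+ncas]
    Dcore = 2 * Ccore @ Ccore.T
    D = Dcore + Cact @ casdm1 @ Cact.T
    hcore = mf.get_hcore()
    one = np.einsum('ij,ij->', D, hcore)
    J = mf.get_j(dm=D)
    vee = 0.5 * np.einsum('ij,ij->', D, J)
    vnn = mol.energy_nuc()
    # grid quantities
    grids = dft.gen_grid.Grids(mol); grids.level = 5; grids.build()
    ni = dft.numint.NumInt()
    ao = ni.eval_ao(mol, grids.coords, deriv=1)
    rho_c = ni.eval_rho(mol, ao, Dcore, xctype='GGA')
    rho_t = ni.eval_rho(mol, ao, D, xctype='GGA')
    phi = ao[0] @ Cact
    rho_a = rho_t[0] - rho_c[0]
    # active on-top pair density: 1/2 d_{uvxy} phi_u phi_v phi_x phi_y
    # pyscf casdm2 is in chemist notation d[p,q,r,s] = <p+ r+ s q> summed spins
    pi_act = 0.5 * np.einsum('pqrs,ip,iq,ir,is->i', casdm2, phi, phi, phi, phi)
    pi = 0.25*rho_c[0]**2 + 0.5*rho_c[0]*rho_a + pi_act
    rho = rho_t[0]
    grad = rho_t[1:4]
    R = np.where(rho > 1e-12, pi / (rho/2)**2, 1.0)
    zt = np.where(R <= 1, np.sqrt(np.clip(1-R, 0, None)), 0.0)
    ra = 0.5*rho*(1+zt); rb = 0.5*rho*(1-zt)
    ga = 0.5*grad*(1+zt); gb = 0.5*grad*(1-zt)
    rho_up = np.vstack([ra, ga])
    rho_dn = np.vstack([rb, gb])
    exc, _ = dft.libxc.eval_xc('PBE,PBE', (rho_up, rho_dn), spin=1)[:2]
    eot = np.einsum('i,i,i->', exc, ra+rb, grids.weights)
    total = one + vee + vnn + eot
    return dict(casci=mc.e_tot, one=one, vee=vee, vnn=vnn, eot=eot, total=total)

if __name__ == "__main__":
    m = gto.M(atom="H 0 0 0; H 0 0 0.74", basis="sto-3g")
    mf = scf.RHF(m); mf.conv_tol = 1e-12; mf.kernel()
    r = tpbe_energy(m, mf, 2, 2)
    print("H2 0.74A STO-3G tPBE:", {k: round(v, 10) for k, v in r.items()})
    m2 = gto.M(atom="H 0 0 0; H 0 0 5.0", basis="sto-3g")
    mf2 = scf.RHF(m2); mf2.conv_tol = 1e-12; mf2.kernel()
    r2 = tpbe_energy(m2, mf2, 2, 2)
    print("H2 5.0A STO-3G tPBE:", {k: round(v, 10) for k, v in r2.items()})
    m3 = gto.M(atom="H 0 0 0; H 0 0 0.74", basis="6-31g")
    mf3 = scf.RHF(m3); mf3.conv_tol = 1e-12; mf3.kernel()
    r3 = tpbe_energy(m3, mf3, 2, 2)
    print("H2 0.74A 6-31G (2e,2o) tPBE:", {k: round(v, 10) for k, v in r3.items()})
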