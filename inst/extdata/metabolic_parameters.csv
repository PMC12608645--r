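reaction,name,value,units,note
r1,vmax_glut,2.45,mM/min,GLUT facilitated glucose transport capacity per unit transporter expression
r1,km_glut,5.0,mM,GLUT half-saturation
r2,vmax_hk,2.5,mM/min,hexokinase capacity per unit enzyme
r2,km_hk,0.15,mM,hexokinase Km for intracellular glucose
r2,ki_hk_g6p,0.3,mM,G6P feedback inhibition constant (Hill n=2)
r2,km_atp_use,0.08,mM,Km for ATP at ATP-consuming kinases
r3,k_pgi,8.0,1/min,phosphoglucose isomerase rate constant
r3,keq_pgi,0.3,dimensionless,G6P/F6P equilibrium ratio
r4,vmax_pfk,4.5,mM/min,phosphofructokinase capacity per unit enzyme; pH-modulated limiting step
r4,km_pfk,0.5,mM,PFK Km for F6P
r4,pfk_amp_base,0.1,dimensionless,PFK activity floor without AMP activation
r4,km_pfk_amp,0.5,mM,AMP allosteric activation constant (Hill n=2)
r4,ki_pfk_atp,3.2,mM,ATP allosteric inhibition of PFK (Hill n=4)
r4,ki_pfk_cit,0.5,mM,citrate inhibition of PFK (glucose sparing; Hill n=2)
r4,ki_pfk_lac,9.0,mM,intracellular lactate feedback inhibition of PFK (Hill n=2)
r5,k_ald,8.0,1/min,aldolase rate constant
r5,keq_ald,0.1,mM,aldolase equilibrium constant
r6,k_tpi,2.0,1/min,triose phosphate isomerase rate constant
r6,keq_tpi,0.045,dimensionless,GAP/DHAP equilibrium ratio
r7,k_gapdh,40.0,1/(mM.min),GAPDH rate constant
r7,keq_gapdh,0.5,dimensionless,GAPDH equilibrium constant
r7,km_gapdh_pi,1.0,mM,GAPDH Km for inorganic phosphate
r8,k_pgk,30.0,1/(mM.min),phosphoglycerate kinase rate constant
r8,keq_pgk,1800.0,dimensionless,PGK equilibrium constant (strongly ATP-forming)
r9,k_pgm,5.0,1/min,phosphoglycerate mutase rate constant
r9,keq_pgm,0.15,dimensionless,PG2/PG3 equilibrium ratio
r10,k_eno,30.0,1/min,enolase rate constant
r10,keq_eno,3.0,dimensionless,PEP/PG2 equilibrium ratio
r11,vmax_pk,8.0,mM/min,pyruvate kinase capacity
r11,km_pk_pep,0.2,mM,PK Km for PEP
r11,km_pk_adp,0.3,mM,PK Km for ADP
r12,k_ldh,150.0,1/(mM.min),LDH mass-action rate constant per unit enzyme
r12,keq_ldh,600.0,dimensionless,LDH equilibrium constant ([lac][NAD+]/[pyr][NADH])
r12,km_ldh_pyr,0.25,mM,LDH saturation constant for pyruvate
r12,km_ldh_lac,1.5,mM,LDH saturation constant for lactate
r13,vmax_gys,0.06,mM/min,glycogen synthesis capacity
r13,km_gys_g6p,0.8,mM,glycogen synthase Km for G6P
r13,gly_cap,20.0,mM,glycogen storage capacity (glucosyl units; Hill n=4 cap)
r13,atp_per_gys,1.0,dimensionless,ATP cost per stored glucosyl unit
r14,vmax_gp,0.4,mM/min,glycogenolysis capacity
r14,km_gp_gly,2.0,mM,glycogen phosphorylase Km
r14,ki_gp_g6p,0.35,mM,G6P inhibition of glycogenolysis (Hill n=2)
r15,vmax_atpase,3.3,mM/min,lumped ATP demand (maintenance + biosynthesis)
r15,km_atpase,0.15,mM,demand saturation constant
r15,ampk_demand_w,0.55,dimensionless,maximal AMPK suppression of the biosynthetic ATP demand
r15,km_ampk_demand,1.0,a.u.,AMPK half-effect on demand suppression (Hill n=2)
r16,k_ak,5.0,1/(mM.min),adenylate kinase rate constant
r16,keq_ak,1.0,dimensionless,adenylate kinase equilibrium constant
r17,vmax_shuttle,9.0,mM/min,malate-aspartate shuttle capacity (lumped)
r17,km_shuttle_nadhc,0.15,mM,shuttle Km for cytosolic NADH
r17,km_shuttle_nadm,1.0,mM,shuttle Km for mitochondrial NAD+
r18,vmax_pdh,1.9,mM/min,pyruvate dehydrogenase capacity per unit enzyme
r18,km_pdh_pyr,0.8,mM,PDH Km for pyruvate
r18,km_nadm,1.0,mM,Km for mitochondrial NAD+ (PDH and TCA dehydrogenases)
r18,ki_pdh_pdk,0.5,a.u.,PDK inhibition constant on PDH activity (Hill n=2)
r18,ki_pdh_accoa,0.2,mM,acetyl-CoA product inhibition of PDH (Hill n=2)
r18,ki_pdk_pyr,1.2,mM,pyruvate inhibition of PDK (feed-forward PDH activation; Hill n=4)
r19,k_cs,20.0,1/(mM.min),citrate synthase rate constant
r19,ki_cs_nadh,3.0,mM,NADH inhibition of citrate synthase (Hill n=2)
r20,k_aco,2.0,1/min,aconitase rate constant
r20,keq_aco,0.07,dimensionless,isocitrate/citrate equilibrium ratio
r21,vmax_mct,2.5,mM/min,MCT lactate-proton symport capacity per unit transporter
r21,km_mct,2.0e-4,mM^2,half-saturation of the lactate*proton driving product
r22,vmax_etc,7.4,mM/min,electron transport + ATP synthase capacity (NADH branch)
r22,km_etc_nadh,1.5,mM,ETC Km for mitochondrial NADH
r22,km_etc_o2,0.024,mM,ETC Km for oxygen (~6 mmHg; tissue-level limitation)
r22,km_etc_adp,0.15,mM,ADP limitation of oxidative phosphorylation (respiratory control)
r24,vmax_etc2,1.5,mM/min,electron transport capacity (FADH2 branch)
r24,km_etc_fadh2,0.3,mM,ETC Km for FADH2
r25,k_idh,20.0,1/min,isocitrate dehydrogenase rate constant
r26,k_kgdh,20.0,1/min,alpha-ketoglutarate dehydrogenase rate constant
r27,k_scs,20.0,1/min,succinyl-CoA synthetase rate constant
r27,km_scs_adp,0.3,mM,SCS Km for ADP
r28,k_sdh,10.0,1/min,succinate dehydrogenase rate constant
r28,km_sdh_fad,0.3,mM,SDH Km for FAD
r29,k_fh,20.0,1/min,fumarase rate constant
r29,keq_fh,4.0,dimensionless,malate/fumarate equilibrium ratio
r30,k_mdh,10.0,1/min,malate dehydrogenase rate constant
r30,km_mdh_oaa,0.05,mM,OAA product inhibition constant
global,p_o_nadh,2.5,ATP/NADH,P/O ratio of the NADH branch
global,p_o_fadh2,1.5,ATP/FADH2,P/O ratio of the FADH2 branch
r23,k_buf_i,0.02,1/min,intracellular pH regulation relaxation rate
r23,ph_i_ref,7.2,pH,intracellular pH set point
global,buffer_ratio,2.0e4,dimensionless,total-to-free proton buffering ratio (cytosol and medium)
global,k_pi_relax,0.5,1/min,phosphate pool relaxation rate
global,pi_ref,5.0,mM,phosphate pool reference concentration
global,ph_mid,6.6,pH,midpoint of the glycolytic pH-inhibition sigmoid
global,ph_steep,3.0,1/pH,steepness of the glycolytic pH-inhibition sigmoid
genes,d_gene,0.0077,1/min,gene expression relaxation rate (half-life 90 min)
genes,d_hif,0.0154,1/min,HIF-1a expression relaxation rate (half-life 45 min)
genes,d_prot,0.0058,1/min,protein degradation rate (half-life 120 min)
genes,k_translate,0.0058,1/min,translation rate per unit expression
genes,hif_a0,0.15,a.u.,HIF-1a basal drive
genes,hif_alac,0.9,a.u.,HIF-1a induction by intracellular lactate
genes,km_hif_lac,10.0,mM,lactate half-activation of HIF-1a (Hill n=2)
genes,hif_ao2,1.6,a.u.,HIF-1a stabilization under hypoxia
genes,km_hif_o2,0.012,mM,oxygen half-repression of HIF-1a (Hill n=2; ~9 mmHg)
genes,kh_gene,0.8,a.u.,HIF-1a protein half-activation for target genes
genes,nh_gene,3.0,dimensionless,Hill coefficient of HIF-1a target regulation
genes,ldh_b0,0.9,a.u.,LDH basal drive
genes,ldh_bh,3.8,a.u.,LDH induction by HIF-1a
genes,ldh_bm,0.3,a.u.,LDH induction by MYC
genes,pdh_b0,0.1,a.u.,PDH basal drive
genes,pdh_bh,1.0,a.u.,PDH drive released when HIF-1a is low
genes,pdh_ampk_w,0.25,dimensionless,AMPK contribution weight to PDH drive
genes,pdk_b0,0.3,a.u.,PDK basal drive
genes,pdk_bh,1.2,a.u.,PDK induction by HIF-1a
genes,glut_b0,0.7,a.u.,GLUT basal drive
genes,glut_bh,1.1,a.u.,GLUT induction by HIF-1a
genes,glut_bm,0.3,a.u.,GLUT induction by MYC
genes,mct_b0,0.6,a.u.,MCT basal drive
genes,mct_bh,1.4,a.u.,MCT induction by HIF-1a
genes,hk_b0,0.8,a.u.,HK basal drive
genes,hk_bh,0.4,a.u.,HK induction by HIF-1a
genes,hk_bm,0.4,a.u.,HK induction by MYC
genes,pfk_b0,0.8,a.u.,PFK basal drive
genes,pfk_bh,0.4,a.u.,PFK induction by HIF-1a
genes,pfk_bm,0.4,a.u.,PFK induction by MYC
genes,myc_b0,1.0,a.u.,MYC constitutive drive
genes,km_myc,1.0,a.u.,MYC half-activation for target genes
genes,ampk_b0,0.25,a.u.,AMPK basal drive
genes,ampk_be,1.5,a.u.,AMPK activation by energy stress
genes,km_ampk_adp,0.8,dimensionless,ADP/ATP ratio half-activation of AMPK
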