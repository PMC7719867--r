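#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
bont_like_p001 - 1050 PF01742 PF01742.5 250 1e-21 120 0.1 1 4 1e-22 1e-21 120 0.1 1 250 11 260 11 260 0.90 -
bont_like_p001 - 1050 PF07952 PF07952.5 250 1e-22 125 0.1 2 4 1e-23 1e-22 125 0.1 1 250 271 520 271 520 0.90 -
bont_like_p001 - 1050 PF07953 PF07953.5 250 1e-23 130 0.1 3 4 1e-24 1e-23 130 0.1 1 250 531 780 531 780 0.90 -
bont_like_p001 - 1050 PF07951 PF07951.5 250 1e-24 135 0.1 4 4 1e-25 1e-24 135 0.1 1 250 791 1040 791 1040 0.90 -
rpoD_like_p002 - 530 PF04542 PF04542.19 250 1e-21 120 0.1 1 2 1e-22 1e-21 120 0.1 1 250 11 260 11 260 0.90 -
rpoD_like_p002 - 530 PF04545 PF04545.19 250 1e-22 125 0.1 2 2 1e-23 1e-22 125 0.1 1 250 271 520 271 520 0.90 -
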