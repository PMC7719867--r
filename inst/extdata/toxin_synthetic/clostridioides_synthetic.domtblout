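#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
tcdB_like_p001 - 1570 PF12918 PF12918.12 250 1e-21 120 0.1 1 6 1e-22 1e-21 120 0.1 1 250 11 260 11 260 0.90 -
tcdB_like_p001 - 1570 PF12919 PF12919.12 250 1e-22 125 0.1 2 6 1e-23 1e-22 125 0.1 1 250 271 520 271 520 0.90 -
tcdB_like_p001 - 1570 PF11713 PF11713.12 250 1e-23 130 0.1 3 6 1e-24 1e-23 130 0.1 1 250 531 780 531 780 0.90 -
tcdB_like_p001 - 1570 PF12920 PF12920.12 250 1e-24 135 0.1 4 6 1e-25 1e-24 135 0.1 1 250 791 1040 791 1040 0.90 -
tcdB_like_p001 - 1570 PF19127 PF19127.12 250 1e-25 140 0.1 5 6 1e-26 1e-25 140 0.1 1 250 1051 1300 1051 1300 0.90 -
tcdB_like_p001 - 1570 PF19127 PF19127.12 250 1e-26 145 0.1 6 6 1e-27 1e-26 145 0.1 1 250 1311 1560 1311 1560 0.90 -
tcdA_like_p002 - 2350 PF12918 PF12918.12 250 1e-21 120 0.1 1 9 1e-22 1e-21 120 0.1 1 250 11 260 11 260 0.90 -
tcdA_like_p002 - 2350 PF12919 PF12919.12 250 1e-22 125 0.1 2 9 1e-23 1e-22 125 0.1 1 250 271 520 271 520 0.90 -
tcdA_like_p002 - 2350 PF11713 PF11713.12 250 1e-23 130 0.1 3 9 1e-24 1e-23 130 0.1 1 250 531 780 531 780 0.90 -
tcdA_like_p002 - 2350 PF12920 PF12920.12 250 1e-24 135 0.1 4 9 1e-25 1e-24 135 0.1 1 250 791 1040 791 1040 0.90 -
tcdA_like_p002 - 2350 PF19127 PF19127.12 250 1e-25 140 0.1 5 9 1e-26 1e-25 140 0.1 1 250 1051 1300 1051 1300 0.90 -
tcdA_like_p002 - 2350 PF19127 PF19127.12 250 1e-26 145 0.1 6 9 1e-27 1e-26 145 0.1 1 250 1311 1560 1311 1560 0.90 -
tcdA_like_p002 - 2350 PF19127 PF19127.12 250 1e-27 150 0.1 7 9 1e-28 1e-27 150 0.1 1 250 1571 1820 1571 1820 0.90 -
tcdA_like_p002 - 2350 PF19127 PF19127.12 250 1e-28 155 0.1 8 9 1e-29 1e-28 155 0.1 1 250 1831 2080 1831 2080 0.90 -
tcdA_like_p002 - 2350 PF19127 PF19127.12 250 1e-29 160 0.1 9 9 1e-30 1e-29 160 0.1 1 250 2091 2340 2091 2340 0.90 -
rpoD_like_p003 - 530 PF04542 PF04542.19 250 1e-21 120 0.1 1 2 1e-22 1e-21 120 0.1 1 250 11 260 11 260 0.90 -
rpoD_like_p003 - 530 PF04545 PF04545.19 250 1e-22 125 0.1 2 2 1e-23 1e-22 125 0.1 1 250 271 520 271 520 0.90 -
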