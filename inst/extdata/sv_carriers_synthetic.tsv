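individual_id	group	sv_ids	wwox_intact_copies
a01	affected	wwox_del	0
a02	affected	wwox_del	0
a03	affected	wwox_del	0
a04	affected	wwox_del	0
a05	affected	wwox_del	0
a06	affected	wwox_del	0
a07	affected	wwox_del	1
a08	affected	wwox_del	1
a09	affected	wwox_del	1
a10	affected	wwox_del	1
a11	affected	wwox_del	1
a12	affected	wwox_del	1
a13	affected	wwox_del	1
a14	affected	wwox_del	1
a15	affected	pitx1_del	2
a16	affected	pitx1_del	2
a17	affected	pitx1_del	2
a18	affected	pitx1_del	2
a19	affected	shc1_dup	2
a20	affected	shc1_dup	2
a21	affected	chr3_del	2
a22	affected	chr3_del	2
a23	affected	wwox_del;pitx1_del	1
a24	affected	wwox_del;pitx1_del	1
a25	affected	wwox_del;sox9_dup	1
a26	affected	wwox_del;sox9_dup	1
a27	affected	wwox_del;wnt6_del	1
a28	affected	wwox_del;chr3_del;wnt6_del	1
a29	affected	pitx1_del;sox9_dup;chr3_del	2
a30	affected	pitx1_del;sox9_dup;chr3_del	2
a31	affected	pitx1_del;sox9_dup;chr3_del	2
a32	affected	pitx1_del;sox9_dup;chr3_del	2
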