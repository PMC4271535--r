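# Nine de novo single-base mutations reported for the Heliconius melpomene
# parent-offspring cross (two F1 parents, 13 focal + 17 bait F2 offspring),
# transcribed from the published mutation table.  The wild-type (wt) and
# mutant (mut) base columns and the per-base read depths are unambiguous in
# the source; positions and individual labels are a best-effort parse of the
# table text.
contig	position	individual	wt	mut	depth_wt	depth_mut	mean_depth_parents	mean_depth_offspring
HE671270	807781	18	A	T	5	15	33.5	26.8
HE670334	715903	3	T	C	13	11	33	28.7
HE670118	16036	103	G	A	11	14	17	25.0
HE670855	108583	7	A	G	25	11	30.5	32.7
HE668834	189330	1	G	A	26	23	58	35.6
HE671384	187868	4	T	A	29	17	40.5	30.8
HE672075	836004	118	G	A	4	12	17	15.6
HE679870	44633	3	G	C	24	13	53	34.2
HE671010	9591	4	T	A	21	21	24.5	22.0
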