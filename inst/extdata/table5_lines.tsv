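# Line-by-site allele calls for four interval genes across the CMS line
# (HZ1A), its restorer (HZ1C), nine maintainer and four restorer lines.
# Columns after role follow the site order of table5_sites.tsv.
line	role	s1	s2	s3	s4	s5	s6	s7	s8	s9
HZ1A	CMS	A	T	G	G	G	T	G	T	G
HZ1C	RESTORER	C	C	A	A	C	G	A	G	A
P21204	MAINTAINER	C	T	G	G	G	G	G	G	G
P21238	MAINTAINER	A	T	G	A	G	T	A	T	G
P21239	MAINTAINER	A	T	G	A	G	T	A	T	G
P21241	MAINTAINER	A	T	G	A	G	T	A	T	G
P21243	MAINTAINER	A	T	G	A	G	T	A	T	G
P21244	MAINTAINER	A	T	G	A	G	T	A	T	G
P21246	MAINTAINER	A	T	G	A	G	T	A	T	G
P21270	MAINTAINER	A	T	G	A	G	T	A	T	G
P21273	MAINTAINER	A	T	G	A	G	T	A	T	G
P21215	RESTORER	A	T	G	A	C	G	A	G	A
P21240	RESTORER	A	T	G	A	C	G	A	G	A
P21247	RESTORER	A	T	G	A	C	G	A	G	A
P21274	RESTORER	A	T	G	A	G	T	A	T	G
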