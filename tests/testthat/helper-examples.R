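# Published example words per pattern: adult SAMPA encoding and the
# segmental child form the across-the-board rule produces.
pattern_examples <- function() {
  read.table(text = '
lang  pattern  word        input             expected
eng   fronting egg         "Eg               "Ed
eng   fronting key         "ki               "ti
eng   fronting back        "b{k              "b{t
eng   fronting king        "kIN              "tIn
eng   fronting go          "go               "do
swe   fronting kaka        ""kA:$ka          ""tA:$ta
swe   fronting gul         "g}:l             "d}:l
swe   fronting gunga       ""g0N$a           ""d0n$a
nor   fronting kopp        "kop              "top
nor   fronting kan         "kAn              "tAn
eng   backing  two         "tu               "ku
eng   backing  puddle      "pV$d@l           "pV$g@l
eng   backing  bottle      "bA$t@l           "bA$k@l
swe   backing  tander      "tEn$d@           "kEN$g@
swe   backing  matta       ""ma$ta           ""ma$ka
nor   backing  odelegge    ""2:$d@$%le$g@    ""2:$g@$%le$g@
eng   stopping suck        "sVk              "tVk
eng   stopping thumb       "TVm              "tVm
swe   stopping vatten      "va$ten           "ba$ten
swe   stopping kors        "kos\'            "kot\'
swe   stopping spoket      ""sp2:$ket        ""p2:$ket
nor   stopping hus         "h}:s             "h}:t
nor   stopping lise        ""li:$s@          ""li:$t@
eng   r_weakening red      "rEd              "jEd
eng   r_weakening borrow   "bA$ro            "bA$jo
swe   r_weakening ramla    ""ram$la          ""jam$la
swe   r_weakening bara     ""bA:$ra          ""bA:$ja
swe   r_weakening dorr     "d9r              "d9j
nor   r_weakening rod      "r2:              "j2:
nor   r_weakening baerer   "b{$r@            "b{$j@
eng   weak_syllable_deletion banana     b@$"n{$n@          "n{$n@
eng   weak_syllable_deletion umbrella   Vm$"brE$l@         "brE$l@
swe   weak_syllable_deletion potatis    pU$"tA:$tIs        "tA:$tIs
swe   weak_syllable_deletion leverpastej le:$v@$pas$"tEj   le:$v@$"tEj
nor   weak_syllable_deletion rakett     ra$"ket            "ket
eng   cluster_reduction bread   "brEd             "bEd
eng   cluster_reduction play    "pleI             "peI
eng   cluster_reduction frog    "frAg             "fAg
eng   cluster_reduction fly     "flaI             "faI
eng   cluster_reduction twice   "twaIs            "taIs
eng   cluster_reduction stop    "stAp             "tAp
eng   cluster_reduction snail   "sneIl            "neIl
eng   cluster_reduction slide   "slaId            "saId
eng   cluster_reduction street  "strit            "tit
eng   cluster_reduction splash  "spl{S            "p{S
swe   cluster_reduction klocka  ""klO$ka          ""kO$ka
swe   cluster_reduction frysa   ""fry:$sa         ""fy:$sa
swe   cluster_reduction brun    "br}:n            "b}:n
swe   cluster_reduction kvall   "kvEl             "kEl
swe   cluster_reduction kniv    "kni:v            "ki:v
swe   cluster_reduction stol    "stu:l            "tu:l
swe   cluster_reduction sno     "sn2:             "n2:
swe   cluster_reduction slass   "slOs             "lOs
swe   cluster_reduction svans   "svans            "vans
swe   cluster_reduction skratta ""skra$ta         ""ka$ta
nor   cluster_reduction klippe  ""kli$p@          ""ki$p@
nor   cluster_reduction briller ""bri$l@          ""bi$l@
nor   cluster_reduction trumme  ""tru$m@          ""tu$m@
nor   cluster_reduction sne     "sne:             "ne:
nor   cluster_reduction stol    "stu:l\'          "tu:l\'
nor   cluster_reduction svale   ""svA$l@          ""vA$l@
nor   cluster_reduction svart   "svAt\'           "vAt\'
nor   cluster_reduction slange  ""s\'l\'A$N@      ""l\'A$N@
', header = TRUE, stringsAsFactors = FALSE, quote = "", comment.char = "")
}
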