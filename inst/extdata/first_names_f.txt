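Marie
Jeanne
Françoise
Monique
Catherine
Nathalie
Isabelle
Jacqueline
Anne
Sylvie
Christiane
Martine
Nicole
Valérie
Sandrine
Chantal
Stéphanie
Sophie
Céline
Christine
Brigitte
Annie
Hélène
Laurence
Véronique
Dominique
Michèle
Danielle
Patricia
Suzanne
Madeleine
Denise
Germaine
Yvonne
Marguerite
Louise
Renée
Marcelle
Simone
Odette
Lucienne
Paulette
Thérèse
Émilie
Julie
Camille
Laura
Léa
Manon
Chloé
Inès
Jade
Louna
Zoé
Clara
Eva
Alice
Lina
Rose
Anna
Juliette
Lucie
Margaux
Mathilde
Océane
Pauline
Romane
Sarah
Clémence
Élise
Amandine
Aurélie
Delphine
Élodie
Florence
Gaëlle
Ingrid
Karine
Laetitia
Maëlle
Nadine
Ophélie
Perrine
Rachel
Sabine
Tiphaine
Vanessa
Virginie
Agnès
Bernadette
Colette
Édith
Fernande
Ginette
Henriette
Irène
Joséphine
Léonie
Mireille
Noémie
Claire
Audrey
Barbara
Caroline
Diane
Estelle
Fanny
Gabrielle
Hortense
Iris
Justine
Maud
Nelly
Solène
Violette
Ambre
Capucine
Eugénie
Salomé
Victoire
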